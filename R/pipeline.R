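# Orchestration: generate/load -> ORFs -> mine -> classify -> derive ->
# profile -> report bundle. All stage results are written as TSV (UTF-8,
# header row, '.' decimals) plus a JSON run manifest, and identical
# config + seed gives byte-identical bundles.

.writeTsv <- function(df, path) {
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.6f", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Run the AMP discovery pipeline
#'
#' Executes the full analysis on either an input transcript FASTA or a
#' seeded synthetic transcriptome, and writes a report bundle to `out_dir`:
#' `candidates.tsv` (mined precursors), `families.tsv` (family calls),
#' `peptides.tsv` (parent + monobasic truncation series for cysteine-free
#' candidates, convertase-released matures for convertase families),
#' `physchem.tsv` (full property table), `truth.tsv` (synthetic runs only)
#' and `manifest.json` (config, seed, package version, input checksums).
#'
#' @param input path to a nucleotide FASTA, or `NULL` when `synthetic` is
#'   given (exactly one of the two must be supplied).
#' @param synthetic list with elements `plants` (list of [plantSpec()]),
#'   `n_decoys`, and optionally `gc` and `sub_rate`.
#' @param seed integer seed; mandatory for synthetic input.
#' @param out_dir output directory (created if needed).
#' @param cfg a [MiningConfig-class].
#' @param rules family rule table.
#' @param min_aa minimum ORF protein length.
#' @param pH pH for the Henderson-Hasselbalch charge column.
#' @param parent_len parent-peptide length for the truncation series.
#' @return (invisibly) a list with the in-memory stage results:
#'   `transcripts`, `truth`, `orfs`, `candidates`, `families`, `peptides`,
#'   `physchem`, `manifest`.
#' @export
runPipeline <- function(input = NULL, synthetic = NULL, seed = NULL,
                        out_dir, cfg = miningConfig(),
                        rules = defaultFamilyRules(), min_aa = 50L,
                        pH = 7.0, parent_len = 20L) {
  if (is.null(input) == is.null(synthetic))
    stop("supply exactly one of 'input' (FASTA path) or 'synthetic' (spec)")
  truth <- NULL
  if (!is.null(synthetic)) {
    if (is.null(seed)) stop("seed is mandatory for synthetic input")
    gen <- generateTranscriptome(synthetic$plants, synthetic$n_decoys,
                                 seed = seed,
                                 gc = if (is.null(synthetic$gc)) 0.45
                                      else synthetic$gc)
    if (!is.null(synthetic$sub_rate) && synthetic$sub_rate > 0)
      gen <- mutatePlants(gen$transcripts, gen$truth, synthetic$sub_rate,
                          seed = seed + 1L)
    transcripts <- gen$transcripts
    truth <- gen$truth
    inputChecksum <- NULL
  } else {
    transcripts <- readFasta(input, "nucleotide")
    inputChecksum <- unname(tools::md5sum(input))
  }

  orfs <- findOrfsSet(transcripts, min_aa = min_aa)
  candidates <- minePrecursors(orfs, cfg)
  families <- classifyCandidates(candidates, rules = rules, cfg = cfg)

  peptides <- list()
  for (i in seq_len(nrow(families))) {
    row <- families[i, ]
    pid <- sprintf("%s|%d-%d|%s", row$transcript_id, row$start, row$end,
                   row$strand)
    if (row$track == "piscidin_like" && !is.na(row$signal_cleavage) &&
        nchar(row$protein) >= row$signal_cleavage + parent_len) {
      par <- parentPeptide(row$protein, row$signal_cleavage,
                           parent_len = parent_len, parent_id = pid)
      peptides[[length(peptides) + 1L]] <-
        truncationSeries(par, id_prefix = paste0(pid, ":Pte"))
    } else if (row$family %in% c("hepcidin", "leap2") &&
               !is.na(row$mature_start)) {
      peptides[[length(peptides) + 1L]] <-
        convertaseMature(row$protein, row$mature_start, parent_id = pid)
    }
  }
  peptides <- if (length(peptides)) do.call(rbind, peptides)
    else data.frame(id = character(), seq = character(),
                    parent_id = character(), rule = character(),
                    cterm_amidated = logical(), stringsAsFactors = FALSE)
  rownames(peptides) <- NULL
  physchem <- if (nrow(peptides)) physchemTable(peptides, pH = pH)
    else data.frame()

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  writeFasta(transcripts, file.path(out_dir, "transcripts.fasta"))
  .writeTsv(candidates, file.path(out_dir, "candidates.tsv"))
  .writeTsv(families, file.path(out_dir, "families.tsv"))
  .writeTsv(peptides, file.path(out_dir, "peptides.tsv"))
  if (nrow(peptides)) .writeTsv(physchem, file.path(out_dir, "physchem.tsv"))
  if (!is.null(truth)) writeGroundTruth(truth, file.path(out_dir, "truth.tsv"))

  manifest <- list(
    package = "AMPminer",
    version = as.character(utils::packageVersion("AMPminer")),
    seed = seed,
    input = if (is.null(input)) NULL else basename(input),
    input_md5 = inputChecksum,
    synthetic = if (is.null(synthetic)) NULL else
      list(n_decoys = synthetic$n_decoys,
           gc = if (is.null(synthetic$gc)) 0.45 else synthetic$gc,
           sub_rate = if (is.null(synthetic$sub_rate)) 0
                      else synthetic$sub_rate,
           plants = lapply(synthetic$plants, unclass)),
    mining = list(anchor_motifs = cfg@anchorMotifs,
                  anchor_window = cfg@anchorWindow,
                  require_all = cfg@requireAll,
                  min_len = cfg@minLen, max_len = cfg@maxLen,
                  max_cys = cfg@maxCys, sp_threshold = cfg@spThreshold),
    min_aa = min_aa, pH = pH, parent_len = parent_len)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")

  invisible(list(transcripts = transcripts, truth = truth, orfs = orfs,
                 candidates = candidates, families = families,
                 peptides = peptides, physchem = physchem,
                 manifest = manifest))
}

#' Synthesis-design table for parent peptides
#'
#' Regenerates, from one or more 20-residue parent peptides, the full
#' synthesis-candidate table: each parent plus its three monobasic
#' truncations, with sequence, length, molecular weight (nearest Da), net
#' charge (table convention) and hydrophobic percentage (truncated).
#'
#' @param parents named character vector of parent peptide sequences; the
#'   names become id stems (each peptide is `<stem><length>`).
#' @return data.frame with columns `id`, `seq`, `n_aa`, `mw_da`,
#'   `net_charge`, `hydrophobicity_pct`.
#' @examples
#' peptideDesignTable(c(`b-Pte` = "FFKRLKNAFKSARQAWRDYK"))
#' @export
peptideDesignTable <- function(parents) {
  if (is.null(names(parents)) || any(!nzchar(names(parents))))
    stop("parents must be a named character vector")
  series <- lapply(names(parents), function(nm) {
    s <- truncationSeries(parents[[nm]], id_prefix = nm)
    if (isTRUE(attr(s, "incomplete")))
      warning("parent ", nm, " has fewer than 3 monobasic truncation sites")
    s
  })
  series <- do.call(rbind, series)
  tab <- physchemTable(series)
  tab[, c("id", "seq", "n_aa", "mw_da", "net_charge", "hydrophobicity_pct")]
}
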