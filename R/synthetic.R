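# Seeded synthetic transcriptomes with planted AMP precursors.
#
# The generator plants family-faithful precursor ORFs (piscidin-like,
# beta-defensin, hepcidin, LEAP-2, NK-lysin) among decoy transcripts and
# returns a ground-truth table, so the mining, classification and derivation
# stages can be scored without sequencing data. Templates are structural
# mimics of the family scaffolds, not copies of any deposited sequence.

# hydrophobic core alphabet of the signal template (strongly Kyte-Doolittle
# positive, excludes the small -3/-1 residues)
.SIG_CORE <- c("L", "I", "V", "F")
# filler alphabet for prodomains/mature scaffolds: no C (cysteine counts are
# diagnostic) and no R (convertase motifs are diagnostic)
.FILLER <- c("A", "G", "S", "T", "N", "Q", "L", "I", "V", "F",
             "W", "H", "K", "D", "E", "Y", "M", "P")
# piscidin mature filler: cysteine-free, cationic-leaning
.PISCIDIN_FILLER <- c("F", "F", "L", "L", "I", "A", "A", "G", "S", "W",
                      "K", "K", "R", "R", "H", "N", "Q", "T", "V", "D")

.CODON_BY_AA <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

.sampleFrom <- function(alphabet, n) alphabet[sample.int(length(alphabet), n, replace = TRUE)]

# encode a protein (no stop) as nucleotides, codons sampled uniformly among
# synonymous options; appends a random stop codon
.encodeProtein <- function(protein, stop = TRUE) {
  res <- strsplit(protein, "", fixed = TRUE)[[1L]]
  codons <- vapply(res, function(a) {
    opts <- .CODON_BY_AA[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1L))
  if (stop) {
    stops <- .CODON_BY_AA[["*"]]
    codons <- c(codons, stops[sample.int(length(stops), 1L)])
  }
  paste(codons, collapse = "")
}

.randomNt <- function(n, gc) {
  if (n == 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# signal peptide matching the (-3,-1) + hydrophobic-core heuristic; piscidin
# signals start with the MAEPG block and carry FLVL inside the core
.signalTemplate <- function(family, signalLen) {
  endBlock <- c("A", .sampleFrom(c("S", "G", "T"), 1L), "A")
  if (family == "piscidin") {
    coreLen <- signalLen - 8L   # MAEPG (5) + A-x-A (3)
    if (coreLen < 6L) stop("signal_len too short for the piscidin template")
    core <- .sampleFrom(.SIG_CORE, coreLen)
    at <- sample.int(coreLen - 3L, 1L)
    core[at:(at + 3L)] <- c("F", "L", "V", "L")
    paste(c("M", "A", "E", "P", "G", core, endBlock), collapse = "")
  } else {
    coreLen <- signalLen - 6L   # M + 2 basic + A-x-A (3)
    if (coreLen < 8L) stop("signal_len too short for the signal template")
    paste(c("M", .sampleFrom(c("K", "R"), 2L), .sampleFrom(.SIG_CORE, coreLen),
            endBlock), collapse = "")
  }
}

# scatter k cysteines into a filler stretch of length n
.cysBlock <- function(n, k, first = NULL) {
  res <- .sampleFrom(.FILLER, n)
  if (!is.null(first)) res[seq_along(first)] <- first
  free <- setdiff(seq_len(n), seq_along(first))
  res[sort(sample(free, k))] <- "C"
  paste(res, collapse = "")
}

#' Specify a family of precursors to plant
#'
#' @param family one of `"piscidin"`, `"defensin"`, `"hepcidin"`, `"leap2"`,
#'   `"nklysin"`.
#' @param count number of transcripts to plant (>= 0).
#' @param signal_len signal-peptide length in residues (default 22).
#' @param mature_len_range integer interval for the piscidin mature-peptide
#'   length (other families use fixed family scaffolds: 42-aa 6-Cys defensin,
#'   26-aa 8-Cys hepcidin behind an RX(K/R)R site, 46-aa 4-Cys LEAP-2 behind
#'   an RXXR site, 75-aa 6-Cys saposin-like NK-lysin block).
#' @return a `plant_spec` list understood by [generateTranscriptome()].
#' @export
plantSpec <- function(family = c("piscidin", "defensin", "hepcidin",
                                 "leap2", "nklysin"),
                      count, signal_len = 22L,
                      mature_len_range = c(38L, 58L)) {
  family <- match.arg(family)
  count <- as.integer(count)
  if (is.na(count) || count < 0L) stop("count must be a non-negative integer")
  mature_len_range <- as.integer(mature_len_range)
  if (length(mature_len_range) != 2L ||
      mature_len_range[1L] > mature_len_range[2L] ||
      mature_len_range[1L] < 10L || mature_len_range[2L] > 120L)
    stop("mature_len_range must be an increasing interval within [10, 120]")
  if (family == "piscidin" && mature_len_range[1L] < 20L)
    stop("piscidin mature_len_range must allow the 20-residue parent peptide")
  structure(list(family = family, count = count,
                 signal_len = as.integer(signal_len),
                 mature_len_range = mature_len_range),
            class = "plant_spec")
}

# build one precursor; returns list(protein, signal, mature, motifs)
.buildPrecursor <- function(spec) {
  sig <- .signalTemplate(spec$family, spec$signal_len)
  switch(spec$family,
    piscidin = {
      n <- sample(seq(spec$mature_len_range[1L], spec$mature_len_range[2L]), 1L)
      mature <- paste(.sampleFrom(.PISCIDIN_FILLER, n), collapse = "")
      list(protein = paste0(sig, mature), signal = sig, mature = mature,
           motifs = c("FLVL", "MAEPG"))
    },
    defensin = {
      mature <- .cysBlock(42L, 6L)
      list(protein = paste0(sig, mature), signal = sig, mature = mature,
           motifs = character())
    },
    hepcidin = {
      pro <- paste(.sampleFrom(.FILLER, 36L), collapse = "")
      site <- "RSKR"
      mature <- .cysBlock(26L, 8L, first = c("Q", "S", "H", "L"))
      list(protein = paste0(sig, pro, site, mature), signal = sig,
           mature = mature, motifs = c("RSKR", "QSHL"))
    },
    leap2 = {
      pro <- paste(.sampleFrom(.FILLER, 30L), collapse = "")
      site <- "RSPR"
      mature <- .cysBlock(46L, 4L)
      list(protein = paste0(sig, pro, site, mature), signal = sig,
           mature = mature, motifs = c("RSPR"))
    },
    nklysin = {
      linker <- paste(.sampleFrom(.FILLER, 25L), collapse = "")
      sap <- .cysBlock(75L, 6L)
      tail <- paste(.sampleFrom(.FILLER, 31L), collapse = "")
      post <- paste0(linker, sap, tail)
      list(protein = paste0(sig, post), signal = sig, mature = post,
           motifs = character())
    })
}

# TRUE when no 6-frame translation of seq contains an anchor motif
.motifFree <- function(seq, motifs = c("FLVL", "MAEPG")) {
  rc <- .revComp(seq)
  for (s in c(seq, rc)) for (f in 0:2) {
    if (nchar(s) < f + 3L) next
    aa <- translateSeq(s, f)
    if (any(vapply(motifs, grepl, logical(1L), aa, fixed = TRUE))) return(FALSE)
  }
  TRUE
}

.decoyTranscript <- function(gc) {
  repeat {
    if (stats::runif(1L) < 0.5) {
      prot <- paste(c("M", .sampleFrom(.AA20, sample(80:180, 1L))), collapse = "")
      seq <- paste0(.randomNt(sample(20:80, 1L), gc), .encodeProtein(prot),
                    .randomNt(sample(20:80, 1L), gc))
    } else {
      seq <- .randomNt(sample(300:900, 1L), gc)
    }
    if (.motifFree(seq)) return(seq)
  }
}

#' Generate a synthetic transcriptome with planted AMP precursors
#'
#' Builds `n_decoys` decoy transcripts (random-codon ORFs or non-coding
#' sequence, rejection-sampled so that no six-frame translation contains an
#' anchor motif) and one transcript per requested plant, each carrying a full
#' precursor ORF (ATG..stop) flanked by random UTRs, on a random strand. The
#' same seed gives byte-identical output.
#'
#' For minus-strand plants the transcript stores the reverse complement of
#' the coding construct; `precursor_start` in the ground truth is always the
#' 0-based offset of the ATG in the *coding orientation* (i.e. on the
#' reverse complement when `strand == "-"`).
#'
#' @param plants list of [plantSpec()] objects (may be empty).
#' @param n_decoys number of decoy transcripts.
#' @param seed integer seed (mandatory; all randomness flows from it).
#' @param gc GC fraction of non-coding/UTR sequence (default 0.45).
#' @return list with `transcripts` (a named [Biostrings::DNAStringSet]) and
#'   `truth` (data.frame with columns `transcript_id`, `family`, `strand`,
#'   `precursor_start`, `signal_peptide`, `mature_peptide`,
#'   `motifs_present`).
#' @examples
#' tx <- generateTranscriptome(list(plantSpec("piscidin", 2)), 5, seed = 1)
#' tx$truth$family
#' @export
generateTranscriptome <- function(plants, n_decoys, seed, gc = 0.45) {
  if (missing(seed)) stop("seed is mandatory")
  n_decoys <- as.integer(n_decoys)
  plants <- lapply(plants, function(p) {
    if (!inherits(p, "plant_spec")) stop("plants must be built with plantSpec()")
    p
  })
  nPlant <- sum(vapply(plants, function(p) p$count, integer(1L)))
  if (nPlant + n_decoys < 1L) stop("need at least one transcript")
  set.seed(as.integer(seed))

  n <- nPlant + n_decoys
  ids <- sprintf("tr%05d", seq_len(n))
  slots <- sample.int(n, nPlant)          # where the plants land
  seqs <- character(n)

  truth <- vector("list", nPlant)
  k <- 0L
  for (spec in plants) {
    for (i in seq_len(spec$count)) {
      k <- k + 1L
      p <- .buildPrecursor(spec)
      utr5 <- .randomNt(sample(20:80, 1L), gc)
      orfNt <- .encodeProtein(p$protein)
      utr3 <- .randomNt(sample(20:80, 1L), gc)
      construct <- paste0(utr5, orfNt, utr3)
      strand <- sample(c("+", "-"), 1L)
      seqs[slots[k]] <-
        if (strand == "+") construct else .revComp(construct)
      truth[[k]] <- data.frame(
        transcript_id = ids[slots[k]],
        family = spec$family,
        strand = strand,
        precursor_start = nchar(utr5),
        signal_peptide = p$signal,
        mature_peptide = p$mature,
        motifs_present = paste(p$motifs, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  for (j in setdiff(seq_len(n), slots)) seqs[j] <- .decoyTranscript(gc)

  truth <- if (nPlant)
    do.call(rbind, truth)[order(match(vapply(truth, `[[`, "", "transcript_id"),
                                      ids)), , drop = FALSE]
  else
    data.frame(transcript_id = character(), family = character(),
               strand = character(), precursor_start = integer(),
               signal_peptide = character(), mature_peptide = character(),
               motifs_present = character(), stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  tx <- Biostrings::DNAStringSet(seqs)
  names(tx) <- ids
  list(transcripts = tx, truth = truth)
}

# protected positions (1-based, on the precursor protein) that mutation must
# not touch: the initiator M, every occurrence of each ground-truth motif,
# every cysteine, and the -3..-1 residues of the signal cleavage site
.protectedMask <- function(protein, signal, motifs) {
  n <- nchar(protein)
  keep <- rep(FALSE, n)
  keep[1L] <- TRUE
  sl <- nchar(signal)
  keep[max(1L, sl - 2L):sl] <- TRUE
  res <- strsplit(protein, "", fixed = TRUE)[[1L]]
  keep[res == "C"] <- TRUE
  for (m in motifs) {
    if (!nzchar(m)) next
    hit <- gregexpr(m, protein, fixed = TRUE)[[1L]]
    if (hit[1L] > 0L)
      for (h in hit) keep[h:(h + nchar(m) - 1L)] <- TRUE
  }
  keep
}

#' Mutate planted precursors outside their conserved scaffold
#'
#' Applies residue substitutions to the planted precursors at rate
#' `sub_rate`, never touching the anchor motifs, the convertase and
#' N-terminal blocks listed in the ground truth, the cysteines of the
#' scaffold, the initiator methionine, or the -3..-1 residues of the signal
#' cleavage site. Substituted residues are re-encoded with random synonymous
#' codons; substitutions never introduce C or R (which would perturb the
#' diagnostic cysteine counts or create spurious convertase sites). Models
#' inter-species divergence concentrated in signal/prodomain filler.
#'
#' @param records transcripts from [generateTranscriptome()].
#' @param truth matching ground-truth data.frame.
#' @param sub_rate per-site substitution probability in `[0, 0.2]`.
#' @param seed integer seed.
#' @return list with updated `transcripts` and `truth`.
#' @export
mutatePlants <- function(records, truth, sub_rate, seed) {
  if (sub_rate < 0 || sub_rate > 0.2) stop("sub_rate must be in [0, 0.2]")
  set.seed(as.integer(seed))
  if (sub_rate == 0 || nrow(truth) == 0L)
    return(list(transcripts = records, truth = truth))
  seqs <- as.character(records)
  for (i in seq_len(nrow(truth))) {
    row <- truth[i, ]
    sq <- seqs[[row$transcript_id]]
    oriented <- if (row$strand == "+") sq else .revComp(sq)
    # precursor protein from the stated offset up to (not including) the stop
    tail <- substr(oriented, row$precursor_start + 1L, nchar(oriented))
    aa <- translateSeq(tail, 0L)
    stopAt <- regexpr("*", aa, fixed = TRUE)
    protein <- substr(aa, 1L, stopAt - 1L)
    motifs <- strsplit(row$motifs_present, ";", fixed = TRUE)[[1L]]
    keep <- .protectedMask(protein, row$signal_peptide, motifs)
    res <- strsplit(protein, "", fixed = TRUE)[[1L]]
    hit <- which(!keep & stats::runif(length(res)) < sub_rate)
    for (h in hit) {
      pool <- setdiff(.AA20, c("C", "R", res[h]))
      res[h] <- pool[sample.int(length(pool), 1L)]
      codon <- .CODON_BY_AA[[res[h]]]
      codon <- codon[sample.int(length(codon), 1L)]
      at <- row$precursor_start + 3L * (h - 1L)
      substr(oriented, at + 1L, at + 3L) <- codon
    }
    newProt <- paste(res, collapse = "")
    matAt <- regexpr(row$mature_peptide, protein, fixed = TRUE)
    truth$signal_peptide[i] <- substr(newProt, 1L, nchar(row$signal_peptide))
    truth$mature_peptide[i] <- substr(newProt, matAt,
                                      matAt + nchar(row$mature_peptide) - 1L)
    seqs[[row$transcript_id]] <-
      if (row$strand == "+") oriented else .revComp(oriented)
  }
  tx <- Biostrings::DNAStringSet(seqs)
  names(tx) <- names(records)
  list(transcripts = tx, truth = truth)
}

#' Write / read a ground-truth table
#'
#' Plain TSV with '.' decimals and a header row; `motifs_present` is
#' semicolon-joined.
#'
#' @param truth data.frame as returned by [generateTranscriptome()].
#' @param path file path.
#' @return `path` (write) or the data.frame (read).
#' @export
writeGroundTruth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(precursor_start = "integer"))
}
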