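#' Locate propeptide-convertase cleavage sites
#'
#' Finds polybasic convertase motifs and reports the 0-based cleavage
#' position immediately after the final arginine. `RXKR_or_RXRR` matches
#' `R-x-[KR]-R` (the site releasing mature hepcidin); `RXXR` matches
#' `R-x-x-R` (the LEAP-2 site). Overlapping matches are all reported.
#'
#' @param protein amino-acid string (length >= 4).
#' @param kind `"RXKR_or_RXRR"` or `"RXXR"`.
#' @return integer vector of 0-based cleavage positions (possibly empty).
#' @examples
#' findConvertaseSite("AARSKRQSHL", "RXKR_or_RXRR")  # 6; downstream "QSHL"
#' @export
findConvertaseSite <- function(protein, kind = c("RXKR_or_RXRR", "RXXR")) {
  kind <- match.arg(kind)
  if (nchar(protein) < 4L) stop("protein must have at least 4 residues")
  pat <- if (kind == "RXKR_or_RXRR") "(?=R.[KR]R)" else "(?=R..R)"
  hit <- gregexpr(pat, protein, perl = TRUE)[[1L]]
  if (hit[1L] < 0L) return(integer())
  as.integer(hit + 3L)   # 1-based motif start + 4 - 1 == 0-based pos after last R
}

#' Cysteine signature of a mature peptide
#'
#' @param mature amino-acid string.
#' @return list with `count` (number of cysteines) and `spacing` (residue
#'   gaps between consecutive cysteines).
#' @examples
#' cysSignature("CACCA")  # count 3, spacing 1, 0
#' @export
cysSignature <- function(mature) {
  pos <- gregexpr("C", mature, fixed = TRUE)[[1L]]
  if (pos[1L] < 0L) return(list(count = 0L, spacing = integer()))
  list(count = length(pos), spacing = as.integer(diff(pos) - 1L))
}

#' Default family rule table
#'
#' Human-editable rule set for the cysteine/convertase-based family calls,
#' one row per family in precedence order (ties resolve to the earlier row):
#' hepcidin > LEAP-2 > defensin > NK-lysin > piscidin-like. Length tolerances
#' are deliberately loose around the canonical scaffolds (26-aa hepcidin,
#' 46-aa LEAP-2, 42-aa defensin); the NK-lysin row is a cysteine-in-window
#' saposin proxy, with `min_len`/`max_len` giving the window bounds.
#'
#' @return data.frame with columns `family`, `mature_cys`, `min_len`,
#'   `max_len`, `convertase`, `nterm_block`, `domain_hint`.
#' @export
defaultFamilyRules <- function() {
  data.frame(
    family = c("hepcidin", "leap2", "defensin", "nklysin", "piscidin_like"),
    mature_cys = c(8L, 4L, 6L, 6L, 0L),
    min_len = c(20L, 40L, 36L, 70L, 10L),
    max_len = c(32L, 52L, 48L, 80L, 120L),
    convertase = c("RXKR_or_RXRR", "RXXR", "", "", ""),
    nterm_block = c("QSHL", "", "", "", ""),
    domain_hint = c("liver-expressed, iron-regulatory",
                    "liver-expressed AMP 2",
                    "beta-defensin directly after signal",
                    "saposin-like cysteine block",
                    "cysteine-free amphipathic helix"),
    stringsAsFactors = FALSE)
}

#' Write / read a family rule table
#' @param rules data.frame as from [defaultFamilyRules()].
#' @param path TSV file path.
#' @return `path` (write) or the rules data.frame (read).
#' @export
writeFamilyRules <- function(rules, path) {
  utils::write.table(rules, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFamilyRules
#' @export
readFamilyRules <- function(path) {
  rules <- utils::read.delim(path, stringsAsFactors = FALSE)
  rules$nterm_block[is.na(rules$nterm_block)] <- ""
  rules$convertase[is.na(rules$convertase)] <- ""
  rules
}

# max cysteine count over sliding windows of length w
.maxCysInWindow <- function(protein, w) {
  res <- strsplit(protein, "", fixed = TRUE)[[1L]]
  isC <- as.integer(res == "C")
  n <- length(isC)
  if (n <= w) return(sum(isC))
  cs <- cumsum(c(0L, isC))
  max(cs[(w + 1L):(n + 1L)] - cs[1L:(n - w + 1L)])
}

#' Classify a precursor into an AMP family
#'
#' Rule-based decision over the precursor sequence:
#' \itemize{
#'   \item hepcidin: an `R-x-[KR]-R` convertase site whose downstream mature
#'     region carries 8 cysteines within the rule's length range (the `QSHL`
#'     N-terminal block is recorded as extra evidence when present);
#'   \item LEAP-2: an `R-x-x-R` site with a 4-cysteine mature region of
#'     about 46 residues;
#'   \item defensin: no prodomain — the post-signal region itself is a
#'     6-cysteine peptide of about 42 residues;
#'   \item NK-lysin: at least 6 cysteines within a 70-80-residue internal
#'     block (saposin-domain proxy);
#'   \item piscidin-like: the anchor motifs plus a cysteine-free mature
#'     region.
#' }
#' Exactly one family is returned (rule-table order gives precedence); a
#' candidate satisfying nothing is `"unclassified"`.
#'
#' @param protein precursor amino-acid string.
#' @param signalCleavage 0-based cleavage position (`NA` when absent).
#' @param motifHits data.frame from [scanMotifs()] (may be empty).
#' @param rules rule table, default [defaultFamilyRules()].
#' @param cfg mining configuration (for the anchor policy of the
#'   piscidin-like rule).
#' @return list with `family`, `evidence` (character vector of satisfied
#'   predicates, empty only for unclassified), `mature_start`, `mature_end`
#'   (0-based half-open, `NA` for unclassified).
#' @export
classifyFamily <- function(protein, signalCleavage = NA_integer_,
                           motifHits = scanMotifs(protein, cfg),
                           rules = defaultFamilyRules(),
                           cfg = miningConfig()) {
  n <- nchar(protein)
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    if (nzchar(r$convertase)) {
      sites <- if (n >= 4L) findConvertaseSite(protein, r$convertase)
               else integer()
      for (s in sites) {
        mature <- substr(protein, s + 1L, n)
        sig <- cysSignature(mature)
        if (sig$count == r$mature_cys &&
            nchar(mature) >= r$min_len && nchar(mature) <= r$max_len) {
          ev <- c(sprintf("%s site at %d", r$convertase, s),
                  sprintf("mature cysteine count %d", sig$count),
                  sprintf("mature length %d in [%d, %d]",
                          nchar(mature), r$min_len, r$max_len))
          if (nzchar(r$nterm_block) && startsWith(mature, r$nterm_block))
            ev <- c(ev, sprintf("N-terminal block %s", r$nterm_block))
          return(list(family = r$family, evidence = ev,
                      mature_start = s, mature_end = n))
        }
      }
    } else if (r$family == "defensin") {
      if (!is.na(signalCleavage)) {
        mature <- substr(protein, signalCleavage + 1L, n)
        sig <- cysSignature(mature)
        if (sig$count == r$mature_cys &&
            nchar(mature) >= r$min_len && nchar(mature) <= r$max_len)
          return(list(family = "defensin",
                      evidence = c("signal peptide, no prodomain",
                                   sprintf("mature cysteine count %d", sig$count),
                                   sprintf("mature length %d in [%d, %d]",
                                           nchar(mature), r$min_len, r$max_len)),
                      mature_start = signalCleavage, mature_end = n))
      }
    } else if (r$family == "nklysin") {
      w <- min(r$max_len, n)
      if (n >= r$min_len && .maxCysInWindow(protein, w) >= r$mature_cys) {
        ms <- if (!is.na(signalCleavage)) signalCleavage else 0L
        return(list(family = "nklysin",
                    evidence = sprintf(
                      ">= %d cysteines within a %d-residue block",
                      r$mature_cys, w),
                    mature_start = ms, mature_end = n))
      }
    } else if (r$family == "piscidin_like") {
      anchorsOk <- if (cfg@requireAll)
        all(cfg@anchorMotifs %in% motifHits$motif) else nrow(motifHits) > 0L
      if (anchorsOk) {
        ms <- if (!is.na(signalCleavage)) signalCleavage else cfg@anchorWindow
        mature <- substr(protein, ms + 1L, n)
        if (cysSignature(mature)$count == 0L &&
            nchar(mature) >= r$min_len && nchar(mature) <= r$max_len)
          return(list(family = "piscidin_like",
                      evidence = c(sprintf("anchor motifs %s",
                                           paste(unique(motifHits$motif),
                                                 collapse = "+")),
                                   "cysteine-free mature region"),
                      mature_start = ms, mature_end = n))
      }
    }
  }
  list(family = "unclassified", evidence = character(),
       mature_start = NA_integer_, mature_end = NA_integer_)
}

#' Classify mined candidates
#'
#' Applies [classifyFamily()] to each row of a [minePrecursors()] result.
#'
#' @param candidates data.frame from [minePrecursors()].
#' @param rules rule table.
#' @param cfg mining configuration.
#' @return `candidates` with added columns `family`, `evidence`
#'   (semicolon-joined), `mature_start`, `mature_end`.
#' @export
classifyCandidates <- function(candidates, rules = defaultFamilyRules(),
                               cfg = miningConfig()) {
  calls <- lapply(seq_len(nrow(candidates)), function(i) {
    classifyFamily(candidates$protein[i],
                   signalCleavage = candidates$signal_cleavage[i],
                   rules = rules, cfg = cfg)
  })
  candidates$family <- vapply(calls, `[[`, "", "family")
  candidates$evidence <- vapply(calls, function(x)
    paste(x$evidence, collapse = "; "), "")
  candidates$mature_start <- vapply(calls, `[[`, 0L, "mature_start")
  candidates$mature_end <- vapply(calls, `[[`, 0L, "mature_end")
  candidates
}
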