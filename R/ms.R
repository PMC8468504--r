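#' In-silico tryptic digestion
#'
#' Cleaves after K or R except when the next residue is P, and enumerates
#' every product with at most `max_missed` missed cleavages. Product masses
#' are monoisotopic with fixed carbamidomethyl-Cys (+57.02146 Da),
#' mirroring an alkylated MS workflow. Products are ordered by
#' `(start, end)`; the zero-missed products tile the parent exactly.
#'
#' @param parent amino-acid string.
#' @param max_missed maximum missed cleavages (default 1).
#' @return data.frame with columns `seq`, `start`, `end` (0-based
#'   half-open), `missed_cleavages`, `mono_mass_alkylated`.
#' @examples
#' trypticDigest("AKPA")$seq  # "AKPA": the KP rule blocks cleavage
#' @export
trypticDigest <- function(parent, max_missed = 1L) {
  res <- .residues(parent, allow = c(.AA20, "X"), what = "parent")
  n <- length(res)
  if (n < 1L) stop("parent must be non-empty")
  cut <- which(res %in% c("K", "R"))        # cleavage after these positions
  cut <- cut[cut < n]
  cut <- cut[res[cut + 1L] != "P"]          # proline blocks cleavage
  bounds <- c(0L, cut, n)                   # 0-based segment boundaries
  nSeg <- length(bounds) - 1L
  rows <- list()
  for (i in seq_len(nSeg)) {
    for (m in 0:min(max_missed, nSeg - i)) {
      s <- bounds[i]; e <- bounds[i + 1L + m]
      rows[[length(rows) + 1L]] <- list(
        seq = substr(parent, s + 1L, e), start = s, end = e,
        missed = m)
    }
  }
  out <- data.frame(
    seq = vapply(rows, `[[`, "", "seq"),
    start = vapply(rows, `[[`, 0L, "start"),
    end = vapply(rows, `[[`, 0L, "end"),
    missed_cleavages = vapply(rows, `[[`, 0L, "missed"),
    stringsAsFactors = FALSE)
  out <- out[order(out$start, out$end), , drop = FALSE]
  out$mono_mass_alkylated <- vapply(out$seq, function(s)
    if (grepl("X", s, fixed = TRUE)) NA_real_
    else monoisotopicMass(s, cys_carbamidomethyl = TRUE), numeric(1L),
    USE.NAMES = FALSE)
  rownames(out) <- NULL
  out
}

#' Match observed peptides against candidate digests
#'
#' Digests each candidate in silico and reports which observed peptide
#' sequences occur among its tryptic products (exact sequence matches).
#'
#' @param candidates data.frame with columns `id` and `seq` (precursor
#'   proteins or peptide candidates), or a named character vector.
#' @param observed character vector of observed peptide sequences
#'   (uppercase).
#' @param max_missed maximum missed cleavages allowed in the digest.
#' @return data.frame with columns `candidate_id`, `peptide`,
#'   `missed_cleavages`, `start`, `end`; zero rows when nothing matches.
#' @export
matchEvidence <- function(candidates, observed, max_missed = 1L) {
  if (is.character(candidates))
    candidates <- data.frame(id = names(candidates), seq = unname(candidates),
                             stringsAsFactors = FALSE)
  stopifnot(all(observed == toupper(observed)))
  rows <- list()
  for (i in seq_len(nrow(candidates))) {
    dig <- trypticDigest(candidates$seq[i], max_missed = max_missed)
    hit <- dig[dig$seq %in% observed, , drop = FALSE]
    if (nrow(hit))
      rows[[length(rows) + 1L]] <- data.frame(
        candidate_id = candidates$id[i], peptide = hit$seq,
        missed_cleavages = hit$missed_cleavages,
        start = hit$start, end = hit$end, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(candidate_id = character(), peptide = character(),
                      missed_cleavages = integer(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fragments per kilobase per million mapped fragments
#'
#' `fpkm = count / ((length_nt / 1000) * (total_mapped / 1e6))`.
#'
#' @param count mapped fragment count(s) for the transcript(s).
#' @param length_nt transcript length(s) in nucleotides (> 0).
#' @param total_mapped total mapped fragments in the library (> 0).
#' @return numeric FPKM value(s).
#' @examples
#' fpkm(10, 1000, 1e6)  # 10
#' @export
fpkm <- function(count, length_nt, total_mapped) {
  if (any(length_nt <= 0)) stop("length_nt must be positive")
  if (any(total_mapped <= 0)) stop("total_mapped must be positive")
  if (any(count < 0)) stop("count must be non-negative")
  count / ((length_nt / 1000) * (total_mapped / 1e6))
}

#' FPKM table from a counts table
#'
#' @param counts data.frame with columns `transcript_id`, `fragment_count`,
#'   `length_nt` (the external counts TSV layout).
#' @param total_mapped library size; defaults to the sum of
#'   `fragment_count`.
#' @return the input with an added `fpkm` column.
#' @export
fpkmTable <- function(counts, total_mapped = sum(counts$fragment_count)) {
  counts$fpkm <- fpkm(counts$fragment_count, counts$length_nt, total_mapped)
  counts
}
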