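#' Parent peptide after the signal cleavage site
#'
#' The synthesis-design rule for cysteine-free precursors whose native
#' mature form is unknown: the first `parent_len` residues after the signal
#' peptide constitute the parent peptide.
#'
#' @param precursor precursor amino-acid string.
#' @param signal_cleavage 0-based position after the last signal residue.
#' @param parent_len parent length in residues (default 20).
#' @param id peptide id (default derived from `parent_len`).
#' @param parent_id id of the precursor.
#' @return one-row data.frame with columns `id`, `seq`, `parent_id`, `rule`,
#'   `cterm_amidated`.
#' @export
parentPeptide <- function(precursor, signal_cleavage, parent_len = 20L,
                          id = NULL, parent_id = "precursor") {
  parent_len <- as.integer(parent_len)
  if (is.na(parent_len) || parent_len < 1L)
    stop("parent_len must be a positive integer")
  if (signal_cleavage + parent_len > nchar(precursor))
    stop("precursor too short: need ", signal_cleavage + parent_len,
         " residues, have ", nchar(precursor))
  seq <- substr(precursor, signal_cleavage + 1L, signal_cleavage + parent_len)
  if (is.null(id)) id <- sprintf("%s-Pte%d", parent_id, parent_len)
  data.frame(id = id, seq = seq, parent_id = parent_id,
             rule = "post_signal_parent", cterm_amidated = FALSE,
             stringsAsFactors = FALSE)
}

#' Monobasic truncation series of a parent peptide
#'
#' Derives shortened synthesis candidates from a parent by truncating at
#' potential monobasic cleavage sites: every strict prefix ending in K or R
#' is a candidate, and the `n_truncations` longest are kept (the parent
#' itself is returned first). Applied to a 20-residue parent this yields the
#' 17/13/10-residue series used for synthetic peptide design. When fewer
#' monobasic prefixes exist than requested, the available ones are returned
#' and the result carries attribute `incomplete = TRUE`.
#'
#' @param parent one-row data.frame from [parentPeptide()] (or a plain
#'   peptide string).
#' @param n_truncations how many truncated forms to keep (default 3).
#' @param id_prefix stem used to name the peptides (default the parent id
#'   with its length suffix removed); each name is `<stem><length>`.
#' @return data.frame of 1 + up to `n_truncations` rows with columns `id`,
#'   `seq`, `parent_id`, `rule`, `cterm_amidated`, ordered by decreasing
#'   length.
#' @examples
#' truncationSeries("FFKRLKNAFKSARQAWRDYK", id_prefix = "b-Pte")$seq
#' @export
truncationSeries <- function(parent, n_truncations = 3L, id_prefix = NULL) {
  if (is.character(parent)) {
    parent <- data.frame(id = sprintf("pep%d", nchar(parent)), seq = parent,
                         parent_id = "precursor", rule = "post_signal_parent",
                         cterm_amidated = FALSE, stringsAsFactors = FALSE)
  }
  seq <- parent$seq[1L]
  n <- nchar(seq)
  if (is.null(id_prefix)) id_prefix <- sub("[0-9]+$", "", parent$id[1L])
  res <- strsplit(seq, "", fixed = TRUE)[[1L]]
  lens <- which(res %in% c("K", "R"))
  lens <- sort(lens[lens < n], decreasing = TRUE)
  keep <- utils::head(lens, n_truncations)
  out <- rbind(
    data.frame(id = sprintf("%s%d", id_prefix, n), seq = seq,
               parent_id = parent$parent_id[1L], rule = "post_signal_parent",
               cterm_amidated = parent$cterm_amidated[1L],
               stringsAsFactors = FALSE),
    if (length(keep)) data.frame(
      id = sprintf("%s%d", id_prefix, keep),
      seq = substr(rep(seq, length(keep)), 1L, keep),
      parent_id = parent$parent_id[1L],
      rule = "monobasic_truncation",
      cterm_amidated = parent$cterm_amidated[1L],
      stringsAsFactors = FALSE))
  rownames(out) <- NULL
  if (length(keep) < n_truncations) attr(out, "incomplete") <- TRUE
  out
}

#' Mature peptide released at a convertase site
#'
#' Slices the precursor from a propeptide-convertase cleavage position (as
#' returned by [findConvertaseSite()]) to its end.
#'
#' @param precursor precursor amino-acid string.
#' @param site_position 0-based cleavage position (after the motif's last R).
#' @param id,parent_id identifiers for the output row.
#' @return one-row data.frame as in [parentPeptide()], `rule =
#'   "convertase_mature"`.
#' @export
convertaseMature <- function(precursor, site_position, id = NULL,
                             parent_id = "precursor") {
  n <- nchar(precursor)
  if (is.na(site_position) || site_position < 0L || site_position >= n)
    stop("convertase site position ", site_position,
         " leaves no mature peptide in a precursor of length ", n)
  seq <- substr(precursor, site_position + 1L, n)
  if (is.null(id)) id <- sprintf("%s-mature", parent_id)
  data.frame(id = id, seq = seq, parent_id = parent_id,
             rule = "convertase_mature", cterm_amidated = FALSE,
             stringsAsFactors = FALSE)
}
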