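#' Translate a nucleotide sequence in a given frame
#'
#' Standard genetic code; codons containing `N` translate to `X`; a trailing
#' incomplete codon is dropped; stop codons appear as `*`.
#'
#' @param seq nucleotide string over `{A,C,G,T,N}`.
#' @param frame 0, 1 or 2 (offset into `seq`).
#' @return amino-acid string.
#' @examples
#' translateSeq("ATGGCT", 0)  # "MA"
#' translateSeq("ATGANT", 0)  # "MX"
#' @export
translateSeq <- function(seq, frame = 0L) {
  seq <- toupper(as.character(seq))
  frame <- as.integer(frame)
  stopifnot(frame %in% 0:2)
  if (grepl("[^ACGTN]", seq))
    stop("illegal base in nucleotide sequence")
  if (nchar(seq) < frame + 3L) stop("sequence too short for frame ", frame)
  n <- (nchar(seq) - frame) %/% 3L
  at <- frame + 3L * (seq_len(n) - 1L) + 1L
  codons <- substring(seq, at, at + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"        # any codon containing N
  paste(aa, collapse = "")
}

# fast reverse complement for plain character sequences (internal)
.revComp <- function(seq) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(seq, "", fixed = TRUE)[[1L]]), collapse = ""))
}

# ORFs within one oriented (already strand-resolved) sequence; returns
# 0-based half-open codon-aligned [start, end) *in that orientation*,
# end includes the stop codon when one closes the ORF
.orfsOneStrand <- function(aaByFrame, ntLen) {
  out <- list()
  for (f in 0:2) {
    aa <- aaByFrame[[f + 1L]]
    if (is.null(aa) || !nzchar(aa)) next
    res <- strsplit(aa, "", fixed = TRUE)[[1L]]
    stops <- which(res == "*")
    starts <- which(res == "M")
    if (!length(starts)) next
    nextStop <- rep(NA_integer_, length(starts))
    if (length(stops)) {
      idx <- findInterval(starts, stops) + 1L  # first stop at/after start
      nextStop <- ifelse(idx <= length(stops), stops[idx], NA_integer_)
    }
    for (i in seq_along(starts)) {
      s <- starts[i]; e <- nextStop[i]
      partial <- is.na(e)
      protein <- if (partial) paste(res[s:length(res)], collapse = "")
                 else paste(res[s:(e - 1L)], collapse = "")
      endCodon <- if (partial) length(res) else e
      out[[length(out) + 1L]] <- list(
        ostart = f + 3L * (s - 1L),         # 0-based, oriented
        oend = f + 3L * endCodon,
        frame = f, partial = partial, protein = protein)
    }
  }
  out
}

#' Find open reading frames in a transcript
#'
#' Enumerates every ATG-initiated ORF in all six frames that either ends at
#' an in-frame stop codon or runs to the transcript end (flagged
#' `partial = TRUE`), keeping proteins of at least `min_aa` residues.
#' Coordinates are 0-based half-open on the forward strand and include the
#' closing stop codon; `frame` is the offset in the coding orientation.
#'
#' The default `min_aa = 50` suppresses decoy micro-ORFs while retaining the
#' smallest full precursor handled here (22-aa signal + 42-aa defensin = 64).
#' Only ATG starts are considered (documented limitation).
#'
#' @param transcript a single-element [Biostrings::DNAStringSet], a
#'   [Biostrings::DNAString], or a nucleotide string; when unnamed the id is
#'   `"transcript"`.
#' @param min_aa minimum protein length (excluding the stop), default 50.
#' @param id transcript id to record (defaults to the element name).
#' @return data.frame with columns `transcript_id`, `start`, `end`, `strand`,
#'   `frame`, `partial`, `protein`, sorted by descending protein length,
#'   ties by (strand, start) ascending.
#' @examples
#' findOrfs("ATGAAATAA", min_aa = 1)$protein  # "MK"
#' @export
findOrfs <- function(transcript, min_aa = 50L, id = NULL) {
  if (inherits(transcript, "DNAStringSet")) {
    stopifnot(length(transcript) == 1L)
    if (is.null(id)) id <- names(transcript)
    transcript <- as.character(transcript[[1L]])
  }
  transcript <- toupper(as.character(transcript))
  if (is.null(id) || !length(id)) id <- "transcript"
  if (grepl("[^ACGTN]", transcript)) stop("illegal base in transcript")
  L <- nchar(transcript)
  rc <- .revComp(transcript)
  aaFwd <- lapply(0:2, function(f)
    if (L >= f + 3L) translateSeq(transcript, f) else "")
  aaRev <- lapply(0:2, function(f)
    if (L >= f + 3L) translateSeq(rc, f) else "")

  rows <- list()
  for (o in .orfsOneStrand(aaFwd, L)) {
    o$strand <- "+"; o$start <- o$ostart; o$end <- o$oend
    rows[[length(rows) + 1L]] <- o
  }
  for (o in .orfsOneStrand(aaRev, L)) {
    o$strand <- "-"; o$start <- L - o$oend; o$end <- L - o$ostart
    rows[[length(rows) + 1L]] <- o
  }
  df <- if (length(rows))
    data.frame(
      transcript_id = id,
      start = vapply(rows, `[[`, 0L, "start"),
      end = vapply(rows, `[[`, 0L, "end"),
      strand = vapply(rows, `[[`, "", "strand"),
      frame = vapply(rows, `[[`, 0L, "frame"),
      partial = vapply(rows, `[[`, TRUE, "partial"),
      protein = vapply(rows, `[[`, "", "protein"),
      stringsAsFactors = FALSE)
  else
    data.frame(transcript_id = character(), start = integer(),
               end = integer(), strand = character(), frame = integer(),
               partial = logical(), protein = character(),
               stringsAsFactors = FALSE)
  df <- df[nchar(df$protein) >= min_aa, , drop = FALSE]
  df <- df[order(-nchar(df$protein), df$strand, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Find ORFs across a transcript set
#'
#' Applies [findOrfs()] to each element of a transcript set and binds the
#' results (per-transcript ordering preserved).
#'
#' @param transcripts a named [Biostrings::DNAStringSet].
#' @inheritParams findOrfs
#' @return data.frame as in [findOrfs()].
#' @export
findOrfsSet <- function(transcripts, min_aa = 50L) {
  parts <- lapply(seq_along(transcripts), function(i)
    findOrfs(as.character(transcripts[[i]]), min_aa = min_aa,
             id = names(transcripts)[i]))
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' ORF proteins as a FASTA-ready set
#'
#' Formats ORF proteins with headers
#' `transcript_id|start-end|strand|frame[|partial]`.
#'
#' @param orfs data.frame from [findOrfs()] / [findOrfsSet()].
#' @return an [Biostrings::AAStringSet] named by the formatted header.
#' @export
orfProteins <- function(orfs) {
  hdr <- sprintf("%s|%d-%d|%s|%d%s", orfs$transcript_id, orfs$start,
                 orfs$end, orfs$strand, orfs$frame,
                 ifelse(orfs$partial, "|partial", ""))
  out <- Biostrings::AAStringSet(orfs$protein)
  names(out) <- hdr
  out
}
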