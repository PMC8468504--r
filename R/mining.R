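#' Scan for anchor motifs near the N-terminus
#'
#' Exact substring matching of each configured anchor motif, keeping all
#' occurrences that start within the anchor window. Positions are 0-based.
#'
#' @param protein amino-acid string.
#' @param cfg a [MiningConfig-class] (default [miningConfig()]).
#' @return data.frame with columns `motif`, `position` (0-based), one row per
#'   occurrence, ordered by position then motif.
#' @examples
#' scanMotifs("MAEPGFLVLLLAGAAA")
#' @export
scanMotifs <- function(protein, cfg = miningConfig()) {
  stopifnot(nzchar(protein))
  window <- substr(protein, 1L, cfg@anchorWindow + max(nchar(cfg@anchorMotifs)) - 1L)
  rows <- list()
  for (m in cfg@anchorMotifs) {
    hit <- gregexpr(paste0("(?=", m, ")"), window, perl = TRUE)[[1L]]
    hit <- hit[hit > 0L & hit - 1L < cfg@anchorWindow]
    for (h in hit)
      rows[[length(rows) + 1L]] <- data.frame(motif = m, position = h - 1L,
                                              stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(motif = character(), position = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$position, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict a signal-peptide cleavage site
#'
#' Transparent von Heijne-style heuristic standing in for an external signal
#' peptide predictor: every candidate cleavage position `c` in `spRange`
#' (cleavage after residue `c`) is scored as the best mean Kyte-Doolittle
#' hydropathy over any contiguous h-window of `hWindow[1]..hWindow[2]`
#' residues inside positions `1..c`, plus a +1 bonus when the residues at -3
#' and -1 relative to the cleavage site are both small (`{A,G,S,C,T}`). The
#' highest-scoring position wins (ties to the smallest `c`); the call is
#' withheld when the best score falls below `spThreshold`.
#'
#' @param protein amino-acid string starting with `M`, length >= 25.
#' @param cfg a [MiningConfig-class] carrying the score parameters.
#' @return list with `cleavage` (0-based position after the last signal
#'   residue, i.e. the signal length, or `NA` when no site passes) and
#'   `score`. Proteins shorter than 25 residues return
#'   `cleavage = NA` with a `"diagnostic"` attribute.
#' @export
predictSignalPeptide <- function(protein, cfg = miningConfig()) {
  res <- strsplit(protein, "", fixed = TRUE)[[1L]]
  n <- length(res)
  if (n < 25L) {
    out <- list(cleavage = NA_integer_, score = NA_real_)
    attr(out, "diagnostic") <- "protein shorter than 25 residues"
    return(out)
  }
  kd <- unname(.KD_SCALE[res])
  kd[is.na(kd)] <- 0   # X and other non-standard residues are neutral
  cs <- cumsum(c(0, kd))
  winMean <- function(lo, hi, w) {  # best mean over windows of length w in [lo,hi]
    if (hi - lo + 1L < w) return(-Inf)
    starts <- lo:(hi - w + 1L)
    max((cs[starts + w] - cs[starts]) / w)
  }
  lo <- cfg@spRange[1L]; hi <- min(cfg@spRange[2L], n - 1L)
  if (hi < lo) return(list(cleavage = NA_integer_, score = NA_real_))
  best <- -Inf; bestC <- NA_integer_
  for (c in lo:hi) {
    h <- max(vapply(cfg@hWindow[1L]:cfg@hWindow[2L],
                    function(w) winMean(1L, c, w), numeric(1L)))
    bonus <- if (res[c - 2L] %in% cfg@smallResidues &&
                 res[c] %in% cfg@smallResidues) 1 else 0
    sc <- h + bonus
    if (sc > best + 1e-12) { best <- sc; bestC <- c }
  }
  if (best < cfg@spThreshold)
    list(cleavage = NA_integer_, score = best)
  else
    list(cleavage = bestC, score = best)
}

#' Mine AMP precursor candidates from ORFs
#'
#' The motif-anchored selection stage. Two tracks are populated:
#' \describe{
#'   \item{`piscidin_like`}{ORFs whose N-terminal window carries the anchor
#'     motifs (all of them when `requireAll`), whose protein length lies in
#'     `[minLen, maxLen]`, and whose mature region (after the predicted
#'     signal cleavage, or after the anchor window when no cleavage is
#'     called) contains at most `maxCys` cysteines — piscidins are
#'     cysteine-free.}
#'   \item{`cysteine_rich`}{ORFs with a predicted signal peptide and at least
#'     4 cysteines after the cleavage site (motif policy not applied).}
#' }
#' Partial ORFs are excluded. Output is sorted by transcript id then start
#' and is invariant to input order.
#'
#' @param orfs data.frame from [findOrfs()] / [findOrfsSet()].
#' @param cfg a [MiningConfig-class].
#' @return data.frame with columns `transcript_id`, `start`, `end`, `strand`,
#'   `frame`, `track`, `motif_hits` (`"MOTIF:pos"` semicolon-joined, 0-based),
#'   `signal_cleavage` (0-based position after the signal, `NA` if absent),
#'   `protein`, `mature_preview` (first 30 residues of the mature region).
#' @export
minePrecursors <- function(orfs, cfg = miningConfig()) {
  empty <- data.frame(transcript_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      frame = integer(), track = character(),
                      motif_hits = character(), signal_cleavage = integer(),
                      protein = character(), mature_preview = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(orfs)) return(empty)
  orfs <- orfs[!orfs$partial, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(orfs))) {
    p <- orfs$protein[i]
    hits <- scanMotifs(p, cfg)
    motifOk <- if (cfg@requireAll)
      all(cfg@anchorMotifs %in% hits$motif) else nrow(hits) > 0L
    sp <- if (nchar(p) >= 25L) predictSignalPeptide(p, cfg)
          else list(cleavage = NA_integer_, score = NA_real_)
    matureFrom <- if (!is.na(sp$cleavage)) sp$cleavage else cfg@anchorWindow
    mature <- substr(p, matureFrom + 1L, nchar(p))
    nCys <- lengths(regmatches(mature, gregexpr("C", mature, fixed = TRUE)))
    track <- NA_character_
    if (motifOk && nchar(p) >= cfg@minLen && nchar(p) <= cfg@maxLen &&
        nCys <= cfg@maxCys) {
      track <- "piscidin_like"
    } else if (!is.na(sp$cleavage)) {
      postSignal <- substr(p, sp$cleavage + 1L, nchar(p))
      nCysPost <- lengths(regmatches(postSignal,
                                     gregexpr("C", postSignal, fixed = TRUE)))
      if (nCysPost >= 4L) track <- "cysteine_rich"
    }
    if (is.na(track)) next
    rows[[length(rows) + 1L]] <- data.frame(
      transcript_id = orfs$transcript_id[i],
      start = orfs$start[i], end = orfs$end[i],
      strand = orfs$strand[i], frame = orfs$frame[i],
      track = track,
      motif_hits = paste(sprintf("%s:%d", hits$motif, hits$position),
                         collapse = ";"),
      signal_cleavage = sp$cleavage,
      protein = p,
      mature_preview = substr(mature, 1L, 30L),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$transcript_id, out$start, out$strand, out$end,
                   out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}
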