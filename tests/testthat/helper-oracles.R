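# Independent oracles used across the suite. These deliberately reimplement
# each computation with a different mechanism from the package code paths.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

randomPeptide <- function(n, alphabet = AA20)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")

randomTranscript <- function(n, withN = FALSE) {
  ab <- if (withN) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  pr <- if (withN) c(.24, .24, .24, .24, .04) else rep(.25, 4)
  paste(sample(ab, n, replace = TRUE, prob = pr), collapse = "")
}

# --- translation: codon table from the classical TCAG-ordered code string ---
.oracleCode <- local({
  aas <- strsplit(paste0("FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
                         "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"),
                  "")[[1L]]
  b <- c("T", "C", "A", "G")
  # first base slowest -> index order matches the code string
  codons <- character(64)
  k <- 0L
  for (b1 in b) for (b2 in b) for (b3 in b) {
    k <- k + 1L
    codons[k] <- paste0(b1, b2, b3)
  }
  stats::setNames(aas, codons)
})

oracleTranslate <- function(seq, frame = 0) {
  out <- character()
  i <- frame + 1
  while (i + 2 <= nchar(seq)) {
    cod <- substr(seq, i, i + 2)
    out <- c(out, if (grepl("N", cod)) "X" else .oracleCode[[cod]])
    i <- i + 3
  }
  paste(out, collapse = "")
}

oracleRevComp <- function(seq)
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(seq, "")[[1L]]), collapse = ""))

# --- ORFs: test every position of every frame on both strands ---
oracleOrfs <- function(transcript, min_aa) {
  L <- nchar(transcript)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") transcript else oracleRevComp(transcript)
    for (p in 0:(L - 3)) {
      if (substr(s, p + 1, p + 3) != "ATG") next
      aa <- character(); q <- p; partial <- TRUE
      while (q + 3 <= L) {
        cod <- substr(s, q + 1, q + 3)
        a <- if (grepl("N", cod)) "X" else .oracleCode[[cod]]
        q <- q + 3
        if (a == "*") { partial <- FALSE; break }
        aa <- c(aa, a)
      }
      if (length(aa) < min_aa) next
      ostart <- p; oend <- q
      rows[[length(rows) + 1L]] <- data.frame(
        start = if (strand == "+") ostart else L - oend,
        end = if (strand == "+") oend else L - ostart,
        strand = strand, frame = p %% 3, partial = partial,
        protein = paste(aa, collapse = ""), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), frame = integer(),
                      partial = logical(), protein = character()))
  out <- do.call(rbind, rows)
  out[order(out$strand, out$start, out$end), , drop = FALSE]
}

# --- monoisotopic mass from elemental composition ---
.elements <- list(
  G = c(C = 2, H = 3, N = 1, O = 1, S = 0),
  A = c(C = 3, H = 5, N = 1, O = 1, S = 0),
  S = c(C = 3, H = 5, N = 1, O = 2, S = 0),
  P = c(C = 5, H = 7, N = 1, O = 1, S = 0),
  V = c(C = 5, H = 9, N = 1, O = 1, S = 0),
  T = c(C = 4, H = 7, N = 1, O = 2, S = 0),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  I = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  N = c(C = 4, H = 6, N = 2, O = 2, S = 0),
  D = c(C = 4, H = 5, N = 1, O = 3, S = 0),
  Q = c(C = 5, H = 8, N = 2, O = 2, S = 0),
  K = c(C = 6, H = 12, N = 2, O = 1, S = 0),
  E = c(C = 5, H = 7, N = 1, O = 3, S = 0),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1, S = 0),
  F = c(C = 9, H = 9, N = 1, O = 1, S = 0),
  R = c(C = 6, H = 12, N = 4, O = 1, S = 0),
  Y = c(C = 9, H = 9, N = 1, O = 2, S = 0),
  W = c(C = 11, H = 10, N = 2, O = 1, S = 0))
.atomMono <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
               O = 15.9949146221, S = 31.97207069)

oracleMonoMass <- function(seq) {
  comp <- Reduce(`+`, .elements[strsplit(seq, "")[[1L]]])
  comp <- comp + c(C = 0, H = 2, N = 0, O = 1, S = 0)  # water
  sum(comp * .atomMono[names(comp)])
}

# --- pH charge / pI: independent group-by-group summation + grid scan ---
oracleCharge <- function(seq, pH, pka = defaultPka(), amidated = FALSE) {
  res <- strsplit(seq, "")[[1L]]
  total <- rep(0, length(pH))
  hh_pos <- function(pKa) 1 / (1 + 10^(pH - pKa))
  hh_neg <- function(pKa) -1 / (1 + 10^(pKa - pH))
  total <- total + hh_pos(pka[["Nterm"]])
  if (!amidated) total <- total + hh_neg(pka[["Cterm"]])
  for (r in res) {
    if (r %in% c("K", "R", "H")) total <- total + hh_pos(pka[[r]])
    if (r %in% c("D", "E", "C", "Y")) total <- total + hh_neg(pka[[r]])
  }
  total
}

oracleGridPI <- function(seq, amidated = FALSE) {
  grid <- seq(0.001, 13.999, by = 0.001)
  z <- oracleCharge(seq, grid, amidated = amidated)
  grid[which.min(abs(z))]
}

# --- smallest arc: 1-degree rotation scan ---
oracleArc <- function(angles) {
  if (!length(angles)) return(NA_real_)
  a <- unique(angles %% 360)
  widths <- vapply(0:359, function(r) max((a - r) %% 360), numeric(1))
  min(widths)
}

# --- tryptic digest: split then merge ---
oracleDigest <- function(parent, max_missed) {
  res <- strsplit(parent, "")[[1L]]
  n <- length(res)
  cuts <- integer()
  for (i in seq_len(n - 1))
    if (res[i] %in% c("K", "R") && res[i + 1] != "P") cuts <- c(cuts, i)
  bounds <- c(0, cuts, n)
  rows <- list()
  for (i in seq_len(length(bounds) - 1)) {
    for (j in i:min(i + max_missed, length(bounds) - 1)) {
      rows[[length(rows) + 1L]] <- data.frame(
        seq = substr(parent, bounds[i] + 1, bounds[j + 1]),
        start = bounds[i], end = bounds[j + 1],
        missed_cleavages = j - i, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$end), , drop = FALSE]
}

# forward-strand coordinates of a ground-truth precursor ORF, and the mined
# row matching it (used to score classification against the truth table)
truthCandidateRow <- function(candidates, truthRow, transcripts) {
  L <- nchar(as.character(transcripts[[truthRow$transcript_id]]))
  rows <- candidates[candidates$transcript_id == truthRow$transcript_id &
                     candidates$strand == truthRow$strand, , drop = FALSE]
  if (truthRow$strand == "+") rows[rows$start == truthRow$precursor_start, ,
                                   drop = FALSE]
  else rows[rows$end == L - truthRow$precursor_start, , drop = FALSE]
}

# the study-condition synthetic mix: 10 piscidin plants + 4 per
# cysteine-rich family among 200 transcripts
studyPlantMix <- function()
  list(plantSpec("piscidin", 10), plantSpec("defensin", 4),
       plantSpec("hepcidin", 4), plantSpec("leap2", 4),
       plantSpec("nklysin", 4))
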