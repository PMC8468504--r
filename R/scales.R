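# Residue-level constant tables shared across the physchem and MS modules.
# All tables are keyed by one-letter code and cover the 20 standard residues.

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Average (isotope-weighted) residue masses, Da.
.AVG_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  Q = 128.1307, E = 129.1155, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

# Monoisotopic residue masses, Da.
.MONO_MASS <- c(
  A = 71.03711,  R = 156.10111, N = 114.04293, D = 115.02694, C = 103.00919,
  Q = 128.05858, E = 129.04259, G = 57.02146,  H = 137.05891, I = 113.08406,
  L = 113.08406, K = 128.09496, M = 131.04049, F = 147.06841, P = 97.05276,
  S = 87.03203,  T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841)

.WATER_AVG  <- 18.0153
.WATER_MONO <- 18.010565
# C-terminal amidation: -OH replaced by -NH2.
.AMIDATION_AVG  <- -0.9847
.AMIDATION_MONO <- -0.98402
# Carbamidomethylation of cysteine (iodoacetamide alkylation), monoisotopic.
.CARBAMIDOMETHYL_MONO <- 57.02146

# Fauchere-Pliska hydrophobicity, as used by the Heliquest server.
.FP_SCALE <- c(
  A = 0.31, R = -1.01, N = -0.60, D = -0.77, C = 1.54,
  Q = -0.22, E = -0.64, G = 0.00, H = 0.13, I = 1.80,
  L = 1.70, K = -0.99, M = 1.23, F = 1.79, P = 0.72,
  S = -0.04, T = 0.26, W = 2.25, Y = 0.96, V = 1.22)

# Kyte-Doolittle hydropathy, used only by the signal-peptide heuristic.
.KD_SCALE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

# Hydrophobic residue set of the "hydrophobicity %" column (G, Y, P, H are
# excluded: beta-Pte20 = 40% rules Y out, gamma-Pte20 = 50% rules G out).
.HYDROPHOBIC_SET <- c("A", "C", "F", "I", "L", "M", "V", "W")

#' Hydrophobicity scales
#'
#' Returns one of the built-in per-residue hydrophobicity tables as a named
#' numeric vector over the 20 standard residues.
#'
#' @param name `"fauchere_pliska"` (Heliquest's scale, used for mean
#'   hydrophobicity and the hydrophobic moment) or `"kyte_doolittle"` (used
#'   by the signal-peptide core score).
#' @return named numeric vector of length 20.
#' @examples
#' hydroScale()[["W"]]
#' @export
hydroScale <- function(name = c("fauchere_pliska", "kyte_doolittle")) {
  switch(match.arg(name),
         fauchere_pliska = .FP_SCALE,
         kyte_doolittle = .KD_SCALE)
}

#' Ionizable-group pKa set
#'
#' The pKa values used by [phCharge()] and [isoelectricPoint()], compatible
#' with the Expasy-style single-value model: one pKa per ionizable side chain
#' plus the free termini.
#'
#' @return named numeric vector with entries `Nterm`, `Cterm`, `D`, `E`, `C`,
#'   `Y`, `H`, `K`, `R`.
#' @export
defaultPka <- function() {
  c(Nterm = 7.5, Cterm = 3.55,
    D = 4.05, E = 4.45, C = 9.0, Y = 10.0,
    H = 5.98, K = 10.0, R = 12.0)
}

# Split a peptide into single-residue codes, validating against the standard
# alphabet. Used by every physchem operation.
.residues <- function(seq, allow = .AA20, what = "peptide") {
  seq <- as.character(seq)
  stopifnot(length(seq) == 1L)
  res <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!(res %in% allow))
  if (length(bad))
    stop(sprintf("illegal residue '%s' at position %d in %s sequence",
                 res[bad[1L]], bad[1L], what))
  res
}
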