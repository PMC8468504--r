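#' @import methods
NULL

#' Mining configuration
#'
#' S4 container for the parameters of the motif-anchored precursor search:
#' which anchor motifs to require near the N-terminus, how the transparent
#' signal-peptide heuristic is scored, and the length/cysteine filters that
#' define the cysteine-free (piscidin-like) track.
#'
#' @slot anchorMotifs character vector of exact amino-acid motifs that must
#'   occur near the N-terminus (default `c("FLVL", "MAEPG")`, the conserved
#'   piscidin signal-peptide blocks).
#' @slot anchorWindow integer; motifs must start within this many residues of
#'   the N-terminus (0-based positions `< anchorWindow`).
#' @slot requireAll logical; if `TRUE` every anchor motif must be present.
#' @slot minLen,maxLen integer bounds on precursor (ORF protein) length for
#'   the piscidin-like track.
#' @slot maxCys integer; maximum cysteine count allowed in the mature region
#'   for the cysteine-free track (piscidins carry none).
#' @slot spThreshold numeric; minimum heuristic score for a signal-peptide
#'   cleavage call.
#' @slot spRange integer(2); candidate cleavage positions (signal lengths)
#'   searched, inclusive.
#' @slot hWindow integer(2); min/max length of the hydrophobic core window
#'   scored with the Kyte-Doolittle scale.
#' @slot smallResidues character; residues accepted at the -3 and -1
#'   positions of the cleavage site (von Heijne-style small residues).
#'
#' @seealso [miningConfig()] for the user-facing constructor,
#'   [minePrecursors()].
#' @exportClass MiningConfig
setClass("MiningConfig",
  representation(
    anchorMotifs = "character",
    anchorWindow = "integer",
    requireAll   = "logical",
    minLen       = "integer",
    maxLen       = "integer",
    maxCys       = "integer",
    spThreshold  = "numeric",
    spRange      = "integer",
    hWindow      = "integer",
    smallResidues = "character"
  )
)

setValidity("MiningConfig", function(object) {
  msg <- character()
  if (length(object@anchorMotifs) < 1L || any(!nzchar(object@anchorMotifs)))
    msg <- c(msg, "anchorMotifs must be non-empty strings")
  if (any(object@anchorMotifs != toupper(object@anchorMotifs)))
    msg <- c(msg, "anchorMotifs must be uppercase")
  if (length(object@anchorWindow) != 1L || is.na(object@anchorWindow))
    msg <- c(msg, "anchorWindow must be a single integer")
  else if (object@anchorWindow < max(nchar(object@anchorMotifs)))
    msg <- c(msg, "anchorWindow must be at least as long as the longest motif")
  if (object@minLen > object@maxLen)
    msg <- c(msg, "minLen must not exceed maxLen")
  if (object@maxCys < 0L) msg <- c(msg, "maxCys must be >= 0")
  if (length(object@spRange) != 2L || object@spRange[1L] > object@spRange[2L])
    msg <- c(msg, "spRange must be an increasing integer pair")
  if (length(object@hWindow) != 2L || object@hWindow[1L] > object@hWindow[2L] ||
      object@hWindow[1L] < 1L)
    msg <- c(msg, "hWindow must be an increasing positive integer pair")
  if (length(msg)) msg else TRUE
})

#' Construct a mining configuration
#'
#' @param anchorMotifs,anchorWindow,requireAll,minLen,maxLen,maxCys,spThreshold,spRange,hWindow,smallResidues
#'   see the slot documentation in [MiningConfig-class].
#' @return a validated [MiningConfig-class] object.
#' @examples
#' cfg <- miningConfig()
#' anchorMotifs(cfg)
#' @export
miningConfig <- function(anchorMotifs = c("FLVL", "MAEPG"),
                         anchorWindow = 30L,
                         requireAll = TRUE,
                         minLen = 60L, maxLen = 120L,
                         maxCys = 0L,
                         spThreshold = 4.0,
                         spRange = c(15L, 30L),
                         hWindow = c(8L, 12L),
                         smallResidues = c("A", "G", "S", "C", "T")) {
  new("MiningConfig",
      anchorMotifs = toupper(as.character(anchorMotifs)),
      anchorWindow = as.integer(anchorWindow),
      requireAll = as.logical(requireAll),
      minLen = as.integer(minLen), maxLen = as.integer(maxLen),
      maxCys = as.integer(maxCys),
      spThreshold = as.numeric(spThreshold),
      spRange = as.integer(spRange),
      hWindow = as.integer(hWindow),
      smallResidues = toupper(as.character(smallResidues)))
}

#' @describeIn MiningConfig-class accessor for the anchor motifs
#' @param x a `MiningConfig`
#' @export
anchorMotifs <- function(x) x@anchorMotifs

#' @describeIn MiningConfig-class accessor for the anchor window (residues)
#' @export
anchorWindow <- function(x) x@anchorWindow

setMethod("show", "MiningConfig", function(object) {
  cat("MiningConfig\n")
  cat("  anchor motifs : ", paste(object@anchorMotifs, collapse = ", "),
      if (object@requireAll) " (all required)" else " (any suffices)", "\n",
      sep = "")
  cat("  anchor window : first ", object@anchorWindow, " residues\n", sep = "")
  cat("  precursor len : [", object@minLen, ", ", object@maxLen, "]\n", sep = "")
  cat("  mature Cys    : <= ", object@maxCys, " (cysteine-free track)\n", sep = "")
  cat("  signal model  : cleavage in [", object@spRange[1L], ", ",
      object@spRange[2L], "], h-window ", object@hWindow[1L], "-",
      object@hWindow[2L], ", threshold ", object@spThreshold, "\n", sep = "")
  invisible(NULL)
})

#' Physicochemical profile of a peptide
#'
#' S4 value object holding every descriptor the pipeline reports for a
#' candidate peptide: masses, the two charge conventions (integer formal
#' charge and the pH-dependent Henderson-Hasselbalch charge), isoelectric
#' point, hydrophobic ratio, mean Fauchere-Pliska hydrophobicity, Eisenberg
#' hydrophobic moment, and the helical-wheel face geometry.
#'
#' @slot seq the peptide sequence.
#' @slot length residue count.
#' @slot avgMass,monoMass average and monoisotopic mass in Da.
#' @slot formalCharge integer charge by the table convention
#'   (#K + #R - #D - #E; His and termini excluded).
#' @slot phCharge numeric Henderson-Hasselbalch net charge at `pH`.
#' @slot pH the pH at which `phCharge` was evaluated.
#' @slot pI isoelectric point (zero of the pH-charge curve).
#' @slot hydrophobicRatio fraction of residues in the hydrophobic set
#'   \{A,C,F,I,L,M,V,W\}.
#' @slot meanH mean Fauchere-Pliska hydrophobicity.
#' @slot muH hydrophobic moment at 100 degrees per residue.
#' @slot wheelAngles per-residue helical-wheel azimuths in degrees.
#' @slot chargedFaceAngle,hydrophobicFaceAngle smallest arc (degrees)
#'   containing all cationic (K/R) or hydrophobic azimuths; `NA` when the
#'   residue class is absent.
#' @slot ctermAmidated logical; whether the C-terminus was treated as amidated.
#'
#' @seealso [peptideProfile()], [physchemTable()]
#' @exportClass PhyschemProfile
setClass("PhyschemProfile",
  representation(
    seq = "character",
    length = "integer",
    avgMass = "numeric",
    monoMass = "numeric",
    formalCharge = "integer",
    phCharge = "numeric",
    pH = "numeric",
    pI = "numeric",
    hydrophobicRatio = "numeric",
    meanH = "numeric",
    muH = "numeric",
    wheelAngles = "numeric",
    chargedFaceAngle = "numeric",
    hydrophobicFaceAngle = "numeric",
    ctermAmidated = "logical"
  )
)

setValidity("PhyschemProfile", function(object) {
  msg <- character()
  if (object@length != nchar(object@seq))
    msg <- c(msg, "length must equal nchar(seq)")
  if (!is.na(object@hydrophobicRatio) &&
      (object@hydrophobicRatio < 0 || object@hydrophobicRatio > 1))
    msg <- c(msg, "hydrophobicRatio must lie in [0, 1]")
  if (length(object@wheelAngles) != object@length)
    msg <- c(msg, "wheelAngles must have one azimuth per residue")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PhyschemProfile", function(object) {
  cat("PhyschemProfile for ", object@seq, " (", object@length, " aa",
      if (object@ctermAmidated) ", C-term amidated", ")\n", sep = "")
  cat(sprintf("  mass      : %.2f Da avg / %.4f Da mono\n",
              object@avgMass, object@monoMass))
  cat(sprintf("  charge    : z = %+d (table), %+0.2f at pH %.1f, pI %.2f\n",
              object@formalCharge, object@phCharge, object@pH, object@pI))
  cat(sprintf("  amphipathy: H = %.3f, muH = %.3f, hydrophobic %d%%\n",
              object@meanH, object@muH,
              as.integer(floor(100 * object@hydrophobicRatio))))
  cat(sprintf("  wheel     : charged face %s deg, hydrophobic face %s deg\n",
              format(object@chargedFaceAngle),
              format(object@hydrophobicFaceAngle)))
  invisible(NULL)
})
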