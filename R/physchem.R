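#' Average (isotope-weighted) peptide mass
#'
#' Sum of average residue masses plus one water (18.0153 Da); C-terminal
#' amidation subtracts 0.9847 Da (OH -> NH2). The table view of this
#' quantity rounds to the nearest dalton.
#'
#' @param seq peptide over the 20 standard residues.
#' @param cterm_amidated logical, default `FALSE`.
#' @return mass in Da (full precision; round with `round()` for the table
#'   view).
#' @examples
#' round(averageMass("FFKRLKNAFKSARQAWRDYK"))  # 2561
#' @export
averageMass <- function(seq, cterm_amidated = FALSE) {
  res <- .residues(seq)
  m <- sum(.AVG_MASS[res]) + .WATER_AVG
  if (cterm_amidated) m <- m + .AMIDATION_AVG
  unname(m)
}

#' Monoisotopic peptide mass
#'
#' Monoisotopic residue masses plus one water (18.010565 Da); optional fixed
#' carbamidomethylation (+57.02146 Da per cysteine, the iodoacetamide
#' alkylation used before tryptic digestion) and C-terminal amidation
#' (-0.98402 Da).
#'
#' @inheritParams averageMass
#' @param cys_carbamidomethyl apply the fixed Cys modification.
#' @return mass in Da.
#' @export
monoisotopicMass <- function(seq, cterm_amidated = FALSE,
                             cys_carbamidomethyl = FALSE) {
  res <- .residues(seq)
  m <- sum(.MONO_MASS[res]) + .WATER_MONO
  if (cys_carbamidomethyl) m <- m + .CARBAMIDOMETHYL_MONO * sum(res == "C")
  if (cterm_amidated) m <- m + .AMIDATION_MONO
  unname(m)
}

#' Formal net charge (table convention)
#'
#' The integer charge convention of the peptide-design table:
#' `z = (#K + #R) - (#D + #E)`. Histidine and the termini are not counted,
#' and amidation does not change z (it only removes the C-terminal carboxyl
#' from the pH-dependent model). Use [phCharge()] for the pH-dependent
#' fractional charge.
#'
#' @inheritParams averageMass
#' @return integer charge.
#' @examples
#' formalCharge("FFRHLKSLWK")  # 3: His is not counted
#' @export
formalCharge <- function(seq, cterm_amidated = FALSE) {
  res <- .residues(seq)
  as.integer(sum(res %in% c("K", "R")) - sum(res %in% c("D", "E")))
}

#' pH-dependent net charge (Henderson-Hasselbalch)
#'
#' Sums the fractional charges of every ionizable group: the N-terminus,
#' the C-terminus (unless amidated) and the D, E, C, Y, H, K, R side chains,
#' each contributing `+1/(1 + 10^(pH - pKa))` (bases) or
#' `-1/(1 + 10^(pKa - pH))` (acids).
#'
#' @inheritParams averageMass
#' @param pH numeric vector of pH values in (0, 14).
#' @param pka named pKa set, default [defaultPka()].
#' @return numeric vector of net charges, one per pH.
#' @export
phCharge <- function(seq, pH = 7.0, cterm_amidated = FALSE,
                     pka = defaultPka()) {
  stopifnot(all(pH > 0 & pH < 14))
  res <- .residues(seq)
  counts <- table(factor(res, levels = .AA20))
  basic <- c(Nterm = 1, H = unname(counts[["H"]]), K = unname(counts[["K"]]),
             R = unname(counts[["R"]]))
  acid <- c(D = unname(counts[["D"]]), E = unname(counts[["E"]]),
            C = unname(counts[["C"]]), Y = unname(counts[["Y"]]),
            Cterm = if (cterm_amidated) 0 else 1)
  vapply(pH, function(p) {
    pos <- sum(basic / (1 + 10^(p - pka[names(basic)])))
    neg <- sum(acid / (1 + 10^(pka[names(acid)] - p)))
    pos - neg
  }, numeric(1L))
}

#' Isoelectric point
#'
#' The pH at which [phCharge()] crosses zero, found by bisection on
#' `[0, 14]` to a tolerance of 1e-3. The pH-charge curve is strictly
#' decreasing in pH, which guarantees the bisection is valid. When the
#' charge never crosses zero (e.g. no acidic group and an amidated
#' C-terminus) the nearer boundary is returned with attribute
#' `boundary = TRUE`.
#'
#' @inheritParams phCharge
#' @param tol bisection tolerance in pH units.
#' @return the pI.
#' @export
isoelectricPoint <- function(seq, cterm_amidated = FALSE,
                             pka = defaultPka(), tol = 1e-3) {
  f <- function(p) phCharge(seq, p, cterm_amidated = cterm_amidated, pka = pka)
  lo <- 1e-6; hi <- 14 - 1e-6
  if (f(lo) < 0) return(structure(0, boundary = TRUE))
  if (f(hi) > 0) return(structure(14, boundary = TRUE))
  while (hi - lo > tol / 2) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Hydrophobic residue ratio
#'
#' Fraction of residues in the hydrophobic set `{A,C,F,I,L,M,V,W}` (G, Y, P
#' and H are excluded from the set). The table view reports the percentage
#' truncated to an integer.
#'
#' @inheritParams averageMass
#' @return fraction in `[0, 1]`.
#' @examples
#' hydrophobicRatio("FFKRLKNAFKSARQAWRDYK")  # 0.40
#' @export
hydrophobicRatio <- function(seq) {
  res <- .residues(seq)
  sum(res %in% .HYDROPHOBIC_SET) / length(res)
}

#' Mean hydrophobicity
#'
#' Arithmetic mean of per-residue scale values over the whole sequence;
#' default scale is Fauchere-Pliska as used by Heliquest.
#'
#' @inheritParams averageMass
#' @param scale named per-residue scale, default
#'   `hydroScale("fauchere_pliska")`.
#' @return mean hydrophobicity (dimensionless).
#' @export
meanHydrophobicity <- function(seq, scale = hydroScale("fauchere_pliska")) {
  res <- .residues(seq)
  if (any(!(res %in% names(scale))))
    stop("residue missing from the hydrophobicity scale")
  mean(scale[res])
}

#' Hydrophobic moment
#'
#' Eisenberg's helical hydrophobic moment: residues are placed around an
#' ideal helix at `delta_deg` degrees per residue (100 for an alpha-helix)
#' and the per-residue hydrophobicities are summed as vectors;
#' `muH = sqrt((sum h_n sin(n d))^2 + (sum h_n cos(n d))^2) / N`.
#'
#' @inheritParams meanHydrophobicity
#' @param delta_deg helical rotation per residue in degrees (default 100).
#' @return the moment magnitude (dimensionless).
#' @export
hydrophobicMoment <- function(seq, scale = hydroScale("fauchere_pliska"),
                              delta_deg = 100) {
  res <- .residues(seq)
  if (length(res) < 2L) stop("need at least 2 residues")
  h <- scale[res]
  if (any(is.na(h))) stop("residue missing from the hydrophobicity scale")
  ang <- (seq_along(res) - 1L) * delta_deg * pi / 180
  sqrt(sum(h * sin(ang))^2 + sum(h * cos(ang))^2) / length(res)
}

# smallest arc (degrees) containing a set of azimuths; NA for empty input
.smallestArc <- function(angles) {
  if (!length(angles)) return(NA_real_)
  a <- sort(unique(angles %% 360))
  if (length(a) == 1L) return(0)
  gaps <- diff(c(a, a[1L] + 360))
  360 - max(gaps)
}

#' Helical-wheel projection geometry
#'
#' Places residue `n` (0-based) at azimuth `(n * delta_deg) mod 360` and
#' reports the smallest arcs containing all cationic (K/R) and all
#' hydrophobic azimuths — the charged and hydrophobic faces of the wheel.
#' A face is `NA` when its residue class is absent.
#'
#' @inheritParams hydrophobicMoment
#' @return list with `wheel_angles` (degrees, one per residue),
#'   `charged_face_angle` and `hydrophobic_face_angle`.
#' @examples
#' helicalWheel("KAAK")$charged_face_angle  # 60
#' @export
helicalWheel <- function(seq, delta_deg = 100) {
  res <- .residues(seq)
  if (length(res) < 2L) stop("need at least 2 residues")
  ang <- ((seq_along(res) - 1L) * delta_deg) %% 360
  list(wheel_angles = ang,
       charged_face_angle = .smallestArc(ang[res %in% c("K", "R")]),
       hydrophobic_face_angle = .smallestArc(ang[res %in% .HYDROPHOBIC_SET]))
}

#' Full physicochemical profile of a peptide
#'
#' Computes every descriptor reported by the pipeline and returns them as a
#' validated [PhyschemProfile-class] object.
#'
#' @inheritParams phCharge
#' @param pH pH at which the Henderson-Hasselbalch charge is evaluated.
#' @return a [PhyschemProfile-class].
#' @examples
#' peptideProfile("FFRHLKSLWKGAKAAFR")
#' @export
peptideProfile <- function(seq, pH = 7.0, cterm_amidated = FALSE) {
  # helix descriptors are undefined for a single residue
  wheel <- if (nchar(seq) >= 2L) helicalWheel(seq)
           else list(wheel_angles = 0, charged_face_angle = NA_real_,
                     hydrophobic_face_angle = NA_real_)
  muH <- if (nchar(seq) >= 2L) hydrophobicMoment(seq) else NA_real_
  new("PhyschemProfile",
      seq = seq,
      length = nchar(seq),
      avgMass = averageMass(seq, cterm_amidated),
      monoMass = monoisotopicMass(seq, cterm_amidated),
      formalCharge = formalCharge(seq, cterm_amidated),
      phCharge = phCharge(seq, pH, cterm_amidated),
      pH = pH,
      pI = as.numeric(isoelectricPoint(seq, cterm_amidated)),
      hydrophobicRatio = hydrophobicRatio(seq),
      meanH = meanHydrophobicity(seq),
      muH = muH,
      wheelAngles = wheel$wheel_angles,
      chargedFaceAngle = wheel$charged_face_angle,
      hydrophobicFaceAngle = wheel$hydrophobic_face_angle,
      ctermAmidated = cterm_amidated)
}

#' Physicochemical table for a set of peptides
#'
#' One row per peptide with both full-precision descriptors and the rounded
#' "table view" columns (`mw_da`: nearest dalton; `hydrophobicity_pct`:
#' percentage truncated to an integer).
#'
#' @param peptides data.frame with columns `id`, `seq` and optionally
#'   `cterm_amidated` (e.g. from [truncationSeries()]), or a character
#'   vector of sequences (named or not).
#' @param pH pH for the Henderson-Hasselbalch charge column.
#' @return data.frame with columns `id`, `seq`, `n_aa`, `mw_da`,
#'   `net_charge`, `hydrophobicity_pct`, `avg_mass`, `mono_mass`,
#'   `ph_charge`, `pI`, `mean_H`, `mu_H`, `charged_face_deg`,
#'   `hydrophobic_face_deg`.
#' @export
physchemTable <- function(peptides, pH = 7.0) {
  if (is.character(peptides)) {
    ids <- if (is.null(names(peptides))) sprintf("pep%d", seq_along(peptides))
           else names(peptides)
    peptides <- data.frame(id = ids, seq = unname(peptides),
                           stringsAsFactors = FALSE)
  }
  if (is.null(peptides$cterm_amidated)) peptides$cterm_amidated <- FALSE
  rows <- lapply(seq_len(nrow(peptides)), function(i) {
    p <- peptideProfile(peptides$seq[i], pH = pH,
                        cterm_amidated = peptides$cterm_amidated[i])
    data.frame(
      id = peptides$id[i], seq = p@seq, n_aa = p@length,
      mw_da = as.integer(round(p@avgMass)),
      net_charge = p@formalCharge,
      hydrophobicity_pct = as.integer(floor(100 * p@hydrophobicRatio)),
      avg_mass = p@avgMass, mono_mass = p@monoMass,
      ph_charge = p@phCharge, pI = p@pI,
      mean_H = p@meanH, mu_H = p@muH,
      charged_face_deg = p@chargedFaceAngle,
      hydrophobic_face_deg = p@hydrophobicFaceAngle,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
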