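test_that("average masses reproduce the designed-peptide values and single residues", {
  expect_equal(round(averageMass("FFKRLKNAFKSARQAWRDYK")), 2561)
  expect_equal(round(averageMass("FFRHLKSLWK")), 1362)
  expect_equal(averageMass("G"), 75.07, tolerance = 0.005)
  # amidation removes one hydroxyl-worth of mass and X has no defined mass
  expect_equal(averageMass("GG", cterm_amidated = TRUE) - averageMass("GG"),
               -0.9847)
  expect_error(averageMass("GXG"), "illegal residue 'X' at position 2")
})

test_that("mass is additive over concatenation up to one water", {
  set.seed(61)
  for (i in 1:40) {
    a <- randomPeptide(sample(1:30, 1)); b <- randomPeptide(sample(1:30, 1))
    expect_equal(averageMass(paste0(a, b)),
                 averageMass(a) + averageMass(b) - 18.0153,
                 tolerance = 1e-9)
    expect_equal(monoisotopicMass(paste0(a, b)),
                 monoisotopicMass(a) + monoisotopicMass(b) - 18.010565,
                 tolerance = 1e-9)
  }
})

test_that("monoisotopic masses agree with an elemental-composition oracle", {
  expect_equal(monoisotopicMass("G"), 75.03203, tolerance = 1e-4)
  expect_equal(monoisotopicMass("C", cys_carbamidomethyl = TRUE) -
               monoisotopicMass("C"), 57.02146, tolerance = 1e-6)
  set.seed(62)
  for (i in 1:50) {
    p <- randomPeptide(10)
    expect_equal(monoisotopicMass(p), oracleMonoMass(p), tolerance = 1e-4)
  }
})

test_that("the table charge convention counts K/R against D/E only", {
  expect_equal(formalCharge("FFKRLKNAFKSARQAWRDYK"), 6L)
  expect_equal(formalCharge("FFRHLKSLWK"), 3L)  # His is not counted
  expect_equal(formalCharge("GGGG"), 0L)
  expect_equal(formalCharge("KDER"), 0L)
})

test_that("the Henderson-Hasselbalch charge behaves at its landmarks", {
  pka <- defaultPka()
  # a His side chain contributes exactly +0.5 at its pKa
  expect_equal(phCharge("GGHGG", pka[["H"]]) - phCharge("GGGGG", pka[["H"]]),
               0.5, tolerance = 1e-9)
  # acid saturation limit: all bases protonated
  expect_equal(phCharge("GKRHKG", 0.001), 1 + 4, tolerance = 0.01)
  # strictly decreasing in pH
  grid <- seq(0.5, 13.5, by = 0.25)
  z <- phCharge("FFKRLKNAFKSARQAWRDYK", grid)
  expect_true(all(diff(z) < 0))
  # matches an independent group-by-group summation
  set.seed(63)
  for (i in 1:30) {
    p <- randomPeptide(sample(3:30, 1))
    expect_equal(phCharge(p, 7), oracleCharge(p, 7), tolerance = 1e-6)
  }
  expect_equal(phCharge("FFKRLKNAFKSARQAWRDYK", 7),
               oracleCharge("FFKRLKNAFKSARQAWRDYK", 7), tolerance = 1e-6)
})

test_that("bisection pI equals a fine grid scan and is monotone in basic residues", {
  expect_equal(isoelectricPoint("GGGG"), oracleGridPI("GGGG"),
               tolerance = 1.1e-3)
  expect_equal(isoelectricPoint("FFKRLKNAFKSARQAWRDYK"),
               oracleGridPI("FFKRLKNAFKSARQAWRDYK"), tolerance = 1.1e-3)
  set.seed(64)
  for (i in 1:20) {
    p <- randomPeptide(sample(5:30, 1))
    expect_gte(isoelectricPoint(paste0(p, "K")) + 1e-9, isoelectricPoint(p))
  }
  # no acidic group + amidated C-terminus: charge never crosses zero
  pi0 <- isoelectricPoint("GKGK", cterm_amidated = TRUE)
  expect_true(isTRUE(attr(pi0, "boundary")))
})

test_that("the hydrophobic set excludes G, Y, P and H", {
  expect_equal(hydrophobicRatio("FFKRLKNAFKSARQAWRDYK"), 8 / 20)
  expect_equal(hydrophobicRatio("FFRHLKSLWKGAKAAFRGAR"), 10 / 20)
  expect_equal(hydrophobicRatio("KKKK"), 0)
  expect_equal(hydrophobicRatio("GYPH"), 0)
})

test_that("mean hydrophobicity and moment reproduce the helix descriptors", {
  expect_equal(meanHydrophobicity("FFRHLKSLWKGAKAAFR"), 0.414,
               tolerance = 0.005)
  expect_equal(meanHydrophobicity("FFRHLKSLWKGAKAAFRGAR"), 0.317,
               tolerance = 0.005)
  expect_equal(meanHydrophobicity("GG"), 0)
  expect_equal(hydrophobicMoment("FFRHLKSLWKGAKAAFR"), 0.647,
               tolerance = 0.005)
  expect_equal(hydrophobicMoment("FFRHLKSLWKGAKAAFRGAR"), 0.556,
               tolerance = 0.005)
  # 18 residues x 100 degrees = 5 full turns: vectors cancel for a homopolymer
  expect_equal(hydrophobicMoment(strrep("L", 18)), 0, tolerance = 1e-9)
  # the moment never exceeds the largest scale magnitude
  set.seed(65)
  fp <- hydroScale("fauchere_pliska")
  for (i in 1:30) {
    mu <- hydrophobicMoment(randomPeptide(sample(2:40, 1)))
    expect_gte(mu, 0)
    expect_lte(mu, max(abs(fp)))
  }
})

test_that("wheel azimuths follow 100-degree steps and faces are smallest arcs", {
  w <- helicalWheel(strrep("A", 19))
  expect_equal(w$wheel_angles[1], 0)
  expect_equal(w$wheel_angles[19], (18 * 100) %% 360)
  expect_equal(helicalWheel("KAAK")$charged_face_angle, 60)
  expect_true(is.na(helicalWheel("AAAA")$charged_face_angle))
  set.seed(66)
  for (i in 1:40) {
    p <- randomPeptide(20)
    w <- helicalWheel(p)
    res <- strsplit(p, "")[[1L]]
    expect_equal(w$charged_face_angle,
                 oracleArc(w$wheel_angles[res %in% c("K", "R")]))
    expect_equal(w$hydrophobic_face_angle,
                 oracleArc(w$wheel_angles[res %in%
                   c("A", "C", "F", "I", "L", "M", "V", "W")]))
  }
})

test_that("the profile object is internally consistent and prints", {
  p <- peptideProfile("FFRHLKSLWKGAKAAFR")
  expect_s4_class(p, "PhyschemProfile")
  expect_equal(p@length, 17L)
  expect_equal(p@formalCharge, 5L)
  expect_output(show(p), "muH = 0.647")
  tab <- physchemTable(c(g17 = "FFRHLKSLWKGAKAAFR", g10 = "FFRHLKSLWK"))
  expect_equal(tab$mw_da, c(2063L, 1362L))
  expect_equal(tab$hydrophobicity_pct, c(52L, 50L))
})
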