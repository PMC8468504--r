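test_that("convertase motifs cleave after the final arginine", {
  expect_equal(findConvertaseSite("AARSKRQSHL", "RXKR_or_RXRR"), 6L)
  expect_equal(findConvertaseSite("AAAA", "RXKR_or_RXRR"), integer())
  expect_equal(findConvertaseSite("RSPRX", "RXXR"), 4L)
  expect_equal(findConvertaseSite("RSPRX", "RXKR_or_RXRR"), integer())
  # overlapping matches are all reported
  expect_equal(findConvertaseSite("RRKRKRR", "RXKR_or_RXRR"), c(4L, 7L))
  expect_error(findConvertaseSite("RKR", "RXXR"), "4 residues")
})

test_that("convertase scanning equals a sliding-window oracle", {
  oracleSites <- function(p, kind) {
    res <- strsplit(p, "")[[1L]]
    out <- integer()
    for (i in seq_len(length(res) - 3)) {
      w <- res[i:(i + 3)]
      hit <- if (kind == "RXXR") w[1] == "R" && w[4] == "R"
             else w[1] == "R" && w[3] %in% c("K", "R") && w[4] == "R"
      if (hit) out <- c(out, i + 3L)
    }
    out
  }
  set.seed(41)
  ab <- c(AA20, rep(c("R", "K"), 8))   # basic-rich so motifs occur
  for (i in 1:250) {
    p <- randomPeptide(sample(4:60, 1), alphabet = ab)
    for (kind in c("RXKR_or_RXRR", "RXXR"))
      expect_equal(findConvertaseSite(p, kind), oracleSites(p, kind))
  }
})

test_that("cysteine signatures count and space correctly", {
  expect_equal(cysSignature("CACCA"), list(count = 3L, spacing = c(1L, 0L)))
  expect_equal(cysSignature("AAAA"), list(count = 0L, spacing = integer()))
  set.seed(42)
  for (i in 1:100) {
    p <- randomPeptide(sample(1:50, 1))
    pos <- which(strsplit(p, "")[[1L]] == "C")
    got <- cysSignature(p)
    expect_equal(got$count, length(pos))
    expect_equal(got$spacing, as.integer(diff(pos) - 1L))
  }
})

test_that("each planted family is called correctly with supporting evidence", {
  gen <- generateTranscriptome(studyPlantMix(), 0, seed = 4)
  orfs <- findOrfsSet(gen$transcripts, min_aa = 50)
  for (i in seq_len(nrow(gen$truth))) {
    r <- gen$truth[i, ]
    hit <- truthCandidateRow(orfs, r, gen$transcripts)
    sp <- predictSignalPeptide(hit$protein[1])
    call <- classifyFamily(hit$protein[1], signalCleavage = sp$cleavage)
    wanted <- if (r$family == "piscidin") "piscidin_like" else r$family
    expect_equal(call$family, wanted)
    expect_gt(length(call$evidence), 0L)
    if (r$family == "hepcidin") {
      expect_true(any(grepl("cysteine count 8", call$evidence)))
      expect_true(any(grepl("QSHL", call$evidence)))
      # the released mature equals the ground truth
      expect_equal(substr(hit$protein[1], call$mature_start + 1,
                          call$mature_end), r$mature_peptide)
    }
    if (r$family == "piscidin")
      expect_true(any(grepl("cysteine-free", call$evidence)))
  }
})

test_that("sequences without any diagnostic pattern stay unclassified, deterministically", {
  p <- paste0("M", strrep("AGSTNQ", 12))
  a <- classifyFamily(p, signalCleavage = NA_integer_)
  expect_equal(a$family, "unclassified")
  expect_length(a$evidence, 0L)
  expect_identical(a, classifyFamily(p, signalCleavage = NA_integer_))
})

test_that("family rules survive a TSV round trip and drive classification", {
  rules <- defaultFamilyRules()
  f <- tempfile(fileext = ".tsv")
  writeFamilyRules(rules, f)
  back <- readFamilyRules(f)
  expect_equal(back, rules)
  # hepcidin-like toy precursor classified under the round-tripped rules
  toy <- paste0("M", strrep("L", 20), "RSKR", "QSHL",
                strrep("C", 8), strrep("A", 14))
  call <- classifyFamily(toy, signalCleavage = NA_integer_, rules = back)
  expect_equal(call$family, "hepcidin")
})
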