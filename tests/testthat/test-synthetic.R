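test_that("decoy-only and plant-only requests produce the right inventory", {
  gen <- generateTranscriptome(list(), 5, seed = 7)
  expect_length(gen$transcripts, 5L)
  expect_equal(nrow(gen$truth), 0L)

  gen2 <- generateTranscriptome(list(plantSpec("piscidin", 10)), 0, seed = 1)
  expect_equal(nrow(gen2$truth), 10L)
  expect_true(all(grepl("FLVL", gen2$truth$motifs_present)))
  expect_true(all(grepl("MAEPG", gen2$truth$motifs_present)))
})

test_that("generation is deterministic: same seed, identical bytes", {
  plants <- list(plantSpec("piscidin", 3), plantSpec("hepcidin", 2))
  a <- generateTranscriptome(plants, 20, seed = 42)
  b <- generateTranscriptome(plants, 20, seed = 42)
  fa <- tempfile(); fb <- tempfile()
  writeFasta(a$transcripts, fa); writeFasta(b$transcripts, fb)
  expect_identical(readLines(fa), readLines(fb))
  expect_identical(a$truth, b$truth)
  ta <- tempfile(); writeGroundTruth(a$truth, ta)
  tb <- tempfile(); writeGroundTruth(b$truth, tb)
  expect_identical(readLines(ta), readLines(tb))
  expect_identical(readGroundTruth(ta), a$truth)
})

test_that("ground-truth peptides are recoverable by translating the stated strand", {
  gen <- generateTranscriptome(studyPlantMix(), 10, seed = 3)
  tx <- as.character(gen$transcripts)
  for (i in seq_len(nrow(gen$truth))) {
    r <- gen$truth[i, ]
    oriented <- if (r$strand == "+") tx[[r$transcript_id]]
                else oracleRevComp(tx[[r$transcript_id]])
    aa <- oracleTranslate(substr(oriented, r$precursor_start + 1,
                                 nchar(oriented)), 0)
    precursor <- sub("\\*.*$", "", aa)
    expect_true(startsWith(precursor, r$signal_peptide))
    expect_true(grepl(r$mature_peptide, precursor, fixed = TRUE))
  }
})

test_that("decoys carry no anchor motif in any N-terminal ORF window", {
  gen <- generateTranscriptome(list(), 60, seed = 13)
  orfs <- findOrfsSet(gen$transcripts, min_aa = 20)
  heads <- substr(orfs$protein, 1, 33)
  expect_false(any(grepl("FLVL", heads)))
  expect_false(any(grepl("MAEPG", heads)))
})

test_that("impossible plant specifications are rejected", {
  expect_error(plantSpec("piscidin", 2, mature_len_range = c(10, 15)),
               "parent")
  expect_error(plantSpec("piscidin", 2, mature_len_range = c(5, 8)),
               "\\[10, 120\\]")
  expect_error(plantSpec("defensin", -1), "non-negative")
  expect_error(generateTranscriptome(list(), 0, seed = 1), "at least one")
})

test_that("mutation respects the protected scaffold and the substitution rate", {
  plants <- list(plantSpec("piscidin", 6), plantSpec("hepcidin", 6))
  gen <- generateTranscriptome(plants, 0, seed = 9)

  # rate zero is the identity
  same <- mutatePlants(gen$transcripts, gen$truth, 0, seed = 1)
  expect_identical(as.character(same$transcripts),
                   as.character(gen$transcripts))

  mut <- mutatePlants(gen$transcripts, gen$truth, 0.10, seed = 2)
  nSub <- 0L; nFree <- 0L
  for (i in seq_len(nrow(gen$truth))) {
    r <- gen$truth[i, ]
    getProt <- function(txset) {
      s <- as.character(txset[[r$transcript_id]])
      o <- if (r$strand == "+") s else oracleRevComp(s)
      sub("\\*.*$", "", oracleTranslate(substr(o, r$precursor_start + 1,
                                               nchar(o)), 0))
    }
    old <- strsplit(getProt(gen$transcripts), "")[[1L]]
    new <- strsplit(getProt(mut$transcripts), "")[[1L]]
    expect_length(new, length(old))
    # independent protected mask: initiator, motifs, cysteines, -3..-1
    keep <- rep(FALSE, length(old))
    keep[1] <- TRUE
    sl <- nchar(r$signal_peptide)
    keep[(sl - 2):sl] <- TRUE
    keep[old == "C"] <- TRUE
    for (m in strsplit(r$motifs_present, ";")[[1L]]) {
      if (!nzchar(m)) next
      h <- gregexpr(m, paste(old, collapse = ""), fixed = TRUE)[[1L]]
      for (p in h) keep[p:(p + nchar(m) - 1)] <- TRUE
    }
    expect_identical(new[keep], old[keep])
    nSub <- nSub + sum(new != old)
    nFree <- nFree + sum(!keep)
  }
  # Hamming distance within 99% binomial bounds of rate x unprotected length
  bounds <- qbinom(c(0.005, 0.995), nFree, 0.10)
  expect_gte(nSub, bounds[1])
  expect_lte(nSub, bounds[2])
  # mutated truth stays internally consistent
  for (i in seq_len(nrow(mut$truth)))
    expect_equal(nchar(mut$truth$mature_peptide[i]),
                 nchar(gen$truth$mature_peptide[i]))
})
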