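test_that("motif scanning reports all windowed occurrences at 0-based positions", {
  hits <- scanMotifs("MAEPGFLVLLLAGAAAAAAAAAAAAAAAAAAAAAA")
  expect_equal(hits$motif, c("MAEPG", "FLVL"))
  expect_equal(hits$position, c(0L, 5L))
  expect_equal(nrow(scanMotifs("MKKTTTTTTTTTTTTTTTTTTTTTTTTT")), 0L)
  # occurrences beyond the window are ignored
  far <- paste0(strrep("G", 40), "FLVLMAEPG")
  expect_equal(nrow(scanMotifs(far)), 0L)
})

test_that("motif scanning equals a naive all-positions scanner", {
  cfg <- miningConfig()
  naive <- function(protein) {
    rows <- list()
    for (m in anchorMotifs(cfg)) {
      for (p in seq_len(min(nchar(protein), anchorWindow(cfg)))) {
        if (substr(protein, p, p + nchar(m) - 1) == m)
          rows[[length(rows) + 1L]] <- data.frame(motif = m, position = p - 1L,
                                                  stringsAsFactors = FALSE)
      }
    }
    if (!length(rows)) return(data.frame(motif = character(),
                                         position = integer(),
                                         stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    out <- out[order(out$position, out$motif), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  set.seed(31)
  # bias the alphabet so motifs actually occur
  ab <- c(AA20, rep(c("F", "L", "V", "M", "A", "E", "P", "G"), 6))
  for (i in 1:300) {
    p <- randomPeptide(sample(10:80, 1), alphabet = ab)
    expect_equal(scanMotifs(p), naive(p))
  }
})

test_that("signal peptide heuristic places the cleavage after the small-residue block", {
  p <- paste0("M", "KK", strrep("L", 12), "AGA", "FFKRLKNAFKSARQAWRDYKAAA")
  sp <- predictSignalPeptide(p)
  expect_equal(sp$cleavage, 18L)    # after the A-G-A block: -3 = A, -1 = A
  # no hydrophobic core -> no call
  acidic <- paste0("M", strrep("D", 30), "AAAAAAAA")
  expect_true(is.na(predictSignalPeptide(acidic)$cleavage))
  # too short -> diagnostic
  short <- predictSignalPeptide("MKKLLLLLLLAGA")
  expect_true(is.na(short$cleavage))
  expect_match(attr(short, "diagnostic"), "shorter")
})

test_that("signal heuristic equals an exhaustive window-scoring oracle", {
  cfg <- miningConfig()
  kd <- hydroScale("kyte_doolittle")
  oracleSP <- function(protein) {
    res <- strsplit(protein, "")[[1L]]
    best <- -Inf; bestC <- NA_integer_
    for (cpos in 15:min(30, length(res) - 1)) {
      h <- -Inf
      for (w in 8:12) {
        if (cpos < w) next
        for (s in 1:(cpos - w + 1))
          h <- max(h, mean(kd[res[s:(s + w - 1)]]))
      }
      bonus <- if (res[cpos - 2] %in% c("A", "G", "S", "C", "T") &&
                   res[cpos] %in% c("A", "G", "S", "C", "T")) 1 else 0
      if (h + bonus > best + 1e-12) { best <- h + bonus; bestC <- cpos }
    }
    list(cleavage = if (best < 4.0) NA_integer_ else bestC, score = best)
  }
  set.seed(32)
  for (i in 1:60) {
    p <- paste0("M", randomPeptide(sample(30:70, 1)))
    got <- predictSignalPeptide(p, cfg)
    want <- oracleSP(p)
    expect_equal(got$cleavage, want$cleavage)
    expect_equal(got$score, want$score, tolerance = 1e-10)
  }
})

test_that("predicted cleavage matches the ground-truth signal length on plants", {
  gen <- generateTranscriptome(studyPlantMix(), 0, seed = 8)
  orfs <- findOrfsSet(gen$transcripts, min_aa = 50)
  ok <- 0L
  for (i in seq_len(nrow(gen$truth))) {
    r <- gen$truth[i, ]
    hit <- truthCandidateRow(orfs, r, gen$transcripts)
    sp <- predictSignalPeptide(hit$protein[1])
    if (!is.na(sp$cleavage) && sp$cleavage == nchar(r$signal_peptide))
      ok <- ok + 1L
  }
  expect_gte(ok / nrow(gen$truth), 0.95)
})

test_that("mining policy and track assignment follow the configuration", {
  expect_equal(nrow(minePrecursors(findOrfs("CCC", min_aa = 1))), 0L)

  # an ORF carrying only FLVL is kept when requireAll = FALSE, dropped otherwise
  protein <- paste0("M", "KK", "FLVL", strrep("L", 8), "AGA",
                    paste(rep("KAGFSN", 8), collapse = ""))
  orf <- data.frame(transcript_id = "t", start = 0L,
                    end = 3L * (nchar(protein) + 1L), strand = "+",
                    frame = 0L, partial = FALSE, protein = protein,
                    stringsAsFactors = FALSE)
  expect_equal(nrow(minePrecursors(orf, miningConfig())), 0L)
  got <- minePrecursors(orf, miningConfig(requireAll = FALSE))
  expect_equal(got$track, "piscidin_like")
  expect_match(got$motif_hits, "FLVL:3")
})

test_that("mining output is invariant to ORF order and shrinks with the window", {
  gen <- generateTranscriptome(studyPlantMix(), 40, seed = 6)
  orfs <- findOrfsSet(gen$transcripts)
  cand <- minePrecursors(orfs)
  set.seed(33)
  shuffled <- orfs[sample.int(nrow(orfs)), , drop = FALSE]
  cand2 <- minePrecursors(shuffled)
  rownames(cand2) <- NULL
  expect_identical(cand, cand2)
  # tightening the anchor window can only shrink the candidate set
  for (w in c(20L, 10L, 5L)) {
    sub <- minePrecursors(orfs, miningConfig(anchorWindow = w))
    key <- function(d) paste(d$transcript_id, d$start, d$strand)
    expect_true(all(key(sub) %in% key(cand)))
  }
})
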