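test_that("proteome simulation is seed-deterministic and spec-faithful", {
  spec <- proteomeSpec(n_background = 5L, background_length = c(100L, 200L),
                       n_cyps = 2L, cyp_length = c(420L, 460L),
                       n_partials = 1L, n_refs = 2L, seed = 601L)
  a <- simulateProteome(spec)
  b <- simulateProteome(spec)
  expect_identical(as.character(a$proteome), as.character(b$proteome))
  expect_identical(a$truth, b$truth)
  # byte-identical FASTA
  fa <- tempfile(); fb <- tempfile()
  writeProteinFasta(a$proteome, fa); writeProteinFasta(b$proteome, fb)
  expect_identical(readLines(fa), readLines(fb))

  expect_equal(sum(a$truth$role == "cyp"), 2L)
  expect_equal(sum(a$truth$role == "cyp_partial"), 1L)
  expect_equal(sum(a$truth$role == "background"), 5L)
  expect_true(all(a$truth$length[a$truth$role == "cyp_partial"] == 250L))
})

test_that("implanted signatures sit exactly at the specified coordinates", {
  # the layout of an annotated 512-aa CYP: K-helix 371, PERF 427, haem 446
  spec <- proteomeSpec(n_background = 0L, n_cyps = 1L, n_partials = 0L,
                       cyp_length = 512L,
                       motif_starts = c(khelix = 371L, perf = 427L, heme = 446L),
                       identity = 100, n_refs = 1L, seed = 602L)
  sim <- simulateProteome(spec)
  sig <- findSignature(sim$proteome[[1L]])
  expect_equal(sig$khelix$start, 371L)
  expect_equal(sig$perf$start, 427L)
  expect_equal(sig$heme$start, 446L)
  # exactly one occurrence of each pattern (no decoys survive rejection)
  pats <- signaturePatterns()
  seq <- as.character(sim$proteome[[1L]])
  expect_equal(nrow(scanMotif(pats$heme, seq)), 1L)
  expect_equal(nrow(scanMotif(pats$perf, seq)), 1L)
  expect_equal(nrow(scanMotif(pats$khelix, seq)), 1L)

  expect_error(proteomeSpec(motif_starts = c(khelix = 400L, perf = 300L,
                                             heme = 446L),
                            cyp_length = 512L), "ordered")
})

test_that("mutateToIdentity hits the target count and honours protection", {
  seq <- randomProtein(100)
  expect_identical(mutateToIdentity(seq, 100), seq)

  mut <- mutateToIdentity(seq, 60, seed = 603L)
  same <- sum(strsplit(seq, "")[[1L]] == strsplit(mut, "")[[1L]])
  expect_equal(same, 60L)

  protected <- 1:30
  mut2 <- mutateToIdentity(seq, 50, protected = protected, seed = 604L)
  expect_equal(substr(mut2, 1, 30), substr(seq, 1, 30))

  expect_error(mutateToIdentity(seq, 20, protected = 1:90), "infeasible")
  # reproducible under the same seed
  expect_identical(mutateToIdentity(seq, 60, seed = 605L),
                   mutateToIdentity(seq, 60, seed = 605L))
})

test_that("background-only proteomes never contain a signature triplet", {
  for (seed in 1:25) {
    sim <- simulateProteome(proteomeSpec(
      n_background = 4L, background_length = c(80L, 250L), n_cyps = 0L,
      n_partials = 0L, n_refs = 1L, seed = seed))
    sigs <- lapply(as.character(sim$proteome), findSignature)
    expect_true(all(vapply(sigs, is.null, logical(1L))))
  }
})

test_that("Cq simulation is deterministic and exact when noise-free", {
  spec <- cqSpec(bio_sd = 0, tech_sd = 0, unstable_sd = 0, seed = 606L)
  a <- simulateCq(spec)
  expect_identical(a$table, simulateCq(spec)$table)

  # all folds 1 and zero noise: every Cq equals its baseline
  flat <- simulateCq(cqSpec(folds = list(), bio_sd = 0, tech_sd = 0,
                            unstable_sd = 0, seed = 607L))
  expect_true(all(flat$table$cq == 22))

  # a 20-fold induction at E = 2 shifts group Cq by exactly log2(20)
  tab <- a$table
  cq_b <- mean(tab$cq[tab$group == "B72" & tab$gene == "tgt1"])
  cq_a <- mean(tab$cq[tab$group == "A72" & tab$gene == "tgt1"])
  expect_equal(cq_a - cq_b, log2(20), tolerance = 1e-12)

  # noise-free pipeline recovers the true fold exactly
  rq <- relativeQuantities(a$table, a$truth$efficiencies)
  res <- computeCNRQ(rq, c("ref1", "ref2"), "A72")
  expect_equal(groupFoldChange(res, "tgt1", "B72")$fold, 20, tolerance = 1e-9)
  # and the dilution series returns the generator's efficiency exactly
  d <- a$dilutions[a$dilutions$gene == "tgt1", ]
  expect_equal(fitEfficiency(d$conc, d$cq, "tgt1")@efficiency, 2,
               tolerance = 1e-9)
})

test_that("unstable references are excluded first by geNorm", {
  sim <- simulateCq(cqSpec(seed = 608L))
  rq <- relativeQuantities(sim$table, sim$truth$efficiencies)
  g <- genormRank(quantityMatrix(rq, c("ref1", "ref2", "ref3")))
  expect_equal(g@ranking[1L], "ref3")
  expect_equal(optimalN(g), 2L)
})

test_that("spec validation rejects impossible generator settings", {
  expect_error(cqSpec(folds = list(tgt1 = c(B72 = -2))), "> 0")
  expect_error(cqSpec(folds = list(tgt1 = c(A72 = 3))), "calibrator")
  expect_error(cqSpec(folds = list(ref1 = c(B72 = 2))), "non-target")
  expect_error(cqSpec(n_bio = 1L), "n_bio")
  expect_error(proteomeSpec(identity = 2), "infeasible")
  expect_error(proteomeSpec(cyp_length = 100L), "too short")
})
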