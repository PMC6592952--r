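test_that("replicate concordance counts ranges against thresholds", {
  # three duplicate sets with ranges 0.1, 0.6, 0.3
  tab <- data.frame(
    sample_id = rep(c("s1", "s2", "s3"), each = 2L),
    group = "A", gene = "g", bio_rep = rep(c("1", "2", "3"), each = 2L),
    tech_rep = rep(c("1", "2"), 3L),
    cq = c(20.0, 20.1, 20.0, 20.6, 20.0, 20.3))
  cc <- replicateConcordance(tab, "technical", thresholds = 0.5)
  expect_equal(unname(cc$fraction_within), 2 / 3)
  expect_equal(cc$n_sets, 3L)

  tab$cq <- rep(20, 6L)
  cc0 <- replicateConcordance(tab, "technical", thresholds = 0.01)
  expect_equal(unname(cc0$fraction_within), 1)
  expect_true(all(cc0$quantiles == 0))

  solo <- tab[c(1L, 3L, 5L), ]
  expect_error(replicateConcordance(solo, "technical"), "at least 2")
})

test_that("technical concordance approaches the closed form for Gaussian noise", {
  # 200 duplicate sets at tech SD 0.2: range = |N(0, sd*sqrt(2))|,
  # P(range <= 0.5) = 1 - 2*pnorm(-0.5 / (0.2*sqrt(2)))
  spec <- cqSpec(target_genes = c("t1", "t2"), stable_refs = c("r1", "r2"),
                 unstable_refs = character(0), groups = "A",
                 calibrator_group = "A", folds = list(),
                 bio_sd = 0.3, tech_sd = 0.2, n_bio = 50L, n_tech = 2L,
                 seed = 501L)
  cc <- replicateConcordance(simulateCq(spec)$table, "technical",
                             thresholds = 0.5)
  expect_equal(cc$n_sets, 200L)
  expected <- 1 - 2 * pnorm(-0.5 / (0.2 * sqrt(2)))
  expect_lt(abs(unname(cc$fraction_within) - expected), 0.05)
})

test_that("standard-curve efficiency comes from OLS on log10 concentration", {
  f <- fitEfficiency(c(1, 1/4, 1/16, 1/64), c(20, 22, 24, 26))
  expect_equal(f@slope, -2 / log10(4), tolerance = 1e-12)
  expect_equal(f@efficiency, 2, tolerance = 1e-12)
  expect_equal(f@r2, 1)

  # hand OLS: perfectly linear, step 2.2 Cq per 4-fold dilution
  f2 <- fitEfficiency(c(1, 1/4, 1/16, 1/64), c(20, 22.2, 24.4, 26.6))
  slope_hand <- -2.2 / log10(4)
  expect_equal(f2@slope, slope_hand, tolerance = 1e-12)
  expect_equal(f2@efficiency, 10^(-1 / slope_hand), tolerance = 1e-12)

  expect_error(fitEfficiency(c(1, 1/4), c(20, 22)), "3 distinct")
  expect_warning(f3 <- fitEfficiency(c(1, 1/4, 1/16), c(20, 19, 18)),
                 "invalid")
  expect_false(f3@valid)
})

test_that("geNorm M matches hand computation and its invariances", {
  q <- cbind(g1 = c(1, 2, 4, 8), g2 = c(2, 4, 8, 16), g3 = c(1, 1, 1, 1))
  rownames(q) <- paste0("s", 1:4)
  m <- genormM(q)
  expect_equal(unname(m["g1"]), mean(c(0, sd(0:3))))
  expect_equal(unname(m["g2"]), unname(m["g1"]))
  expect_equal(unname(m["g3"]), sd(0:3))

  # proportional profiles attain M = 0 for the pair
  expect_equal(unname(genormM(q[, c("g1", "g2")])), c(0, 0))

  # scaling one gene's quantities leaves M unchanged
  q2 <- q; q2[, "g3"] <- q2[, "g3"] * 10
  expect_equal(genormM(q2), m)

  expect_error(genormM(q * 0), "positive")
})

test_that("geNorm ranking excludes unstable genes first and picks n", {
  q <- cbind(g1 = c(1, 2, 4, 8), g2 = c(2, 4, 8, 16), g3 = c(1, 1, 1, 1))
  rownames(q) <- paste0("s", 1:4)
  r <- genormRank(q)
  expect_equal(r@ranking, "g3")
  expect_equal(stabilityOrder(r), c("g1", "g2", "g3"))
  # V(2/3) by hand: sd of (x + 0.5)/3 over x = 0:3
  expect_equal(unname(vSeries(r)["2/3"]), sd((0:3 + 0.5) / 3))
  expect_equal(optimalN(r), 2L)

  # all genes mutually proportional: M = 0, any V = 0, two references do
  prop <- cbind(a = c(1, 2, 4), b = c(2, 4, 8), c = c(4, 8, 16))
  rownames(prop) <- paste0("s", 1:3)
  rp <- genormRank(prop)
  expect_equal(unname(mValues(rp)), c(0, 0, 0))
  expect_equal(unname(vSeries(rp)), 0)
  expect_equal(optimalN(rp), 2L)
  # ties broken by gene name: alphabetically later leaves first
  expect_equal(rp@ranking, "c")

  expect_error(genormRank(prop[, 1:2]), "at least 3")
})

test_that("adding an exact copy of a gene makes the copy pair most stable", {
  set.seed(502)
  for (i in 1:5) {
    q <- matrix(exp(rnorm(24)), 6, 4,
                dimnames = list(paste0("s", 1:6), paste0("g", 1:4)))
    qq <- cbind(q, g_copy = q[, "g2"])
    m <- genormM(qq)
    expect_equal(unname(m["g_copy"]), unname(m["g2"]))
    others <- setdiff(colnames(qq), c("g2", "g_copy"))
    expect_lte(max(m[c("g2", "g_copy")]), min(m[others]))
  }
})

test_that("relative quantities follow RQ = E^(Cq_ref - Cq)", {
  mk <- function(cq1, cq2) data.frame(
    sample_id = c("s1", "s2"), group = c("A", "B"), gene = "g",
    bio_rep = c("1", "1"), tech_rep = "1", cq = c(cq1, cq2))
  rq <- relativeQuantities(mk(20, 23), c(g = 2))
  # Cq_ref = 21.5 -> RQ = 2^1.5, 2^-1.5
  expect_equal(rq$rq, c(2^1.5, 2^-1.5))

  rq2 <- relativeQuantities(mk(20, 23), c(g = 1.87))
  expect_equal(rq2$rq[1] / rq2$rq[2], 1.87^3)
  expect_lt(rq2$rq[1] / rq2$rq[2], 8)  # lower E compresses the spread vs 2^3

  same <- relativeQuantities(mk(21, 21), c(g = 2))
  expect_equal(same$rq, c(1, 1))

  expect_error(relativeQuantities(mk(20, 23), c(other = 2)), "gene: g")
  expect_warning(relativeQuantities(mk(20, 23)), "E = 2")
})

test_that("CNRQ equals the hand-computed oracle and normalises the calibrator", {
  # 2 samples, 1 target, 2 references, hand arithmetic:
  # s1: NF = gm(2, 8) = 4, NRQ = 4/4 = 1; s2: NF = gm(3, 3) = 3, NRQ = 9/3 = 3
  # calibrator = group of s1 -> CNRQ = (1, 3)
  rq <- rqTable(sample_id = rep(c("s1", "s2"), each = 3L),
                group = rep(c("CAL", "TRT"), each = 3L),
                gene = rep(c("tgt", "r1", "r2"), 2L),
                rq = c(4, 2, 8, 9, 3, 3))
  res <- computeCNRQ(rq, c("r1", "r2"), "CAL")
  s <- sampleQuantities(res)
  expect_equal(s$nf[s$sample_id == "s1"], rep(4, 3L))
  expect_equal(s$cnrq[s$gene == "tgt"], c(1, 3))

  # single reference equal to the target: NRQ = 1 everywhere
  rq1 <- rqTable(c("s1", "s2"), c("CAL", "TRT"), "g", c(5, 7))
  res1 <- computeCNRQ(rq1, "g", "CAL")
  expect_equal(sampleQuantities(res1)$nrq, c(1, 1))

  # calibrating against the whole dataset: geomean of all CNRQs is 1
  rq$group <- "ALL"
  resall <- computeCNRQ(rq, c("r1", "r2"), "ALL")
  sall <- sampleQuantities(resall)
  for (g in unique(sall$gene))
    expect_equal(geomMeanOracle(sall$cnrq[sall$gene == g]), 1, tolerance = 1e-12)

  expect_error(computeCNRQ(rq[rq$gene != "r1", ], c("r1", "r2"), "ALL"),
               "reference gene 'r1' missing")
  expect_error(computeCNRQ(rq, c("r1", "r2"), "NOPE"), "calibrator")
})

test_that("per-sample rescaling is absorbed by the normalisation factor", {
  set.seed(503)
  genes <- c("tgt", "r1", "r2")
  rq <- rqTable(sample_id = rep(paste0("s", 1:4), each = 3L),
                group = rep(c("CAL", "CAL", "TRT", "TRT"), each = 3L),
                gene = rep(genes, 4L), rq = exp(rnorm(12)))
  res <- computeCNRQ(rq, c("r1", "r2"), "CAL")
  rq2 <- rq
  rq2$rq[rq2$sample_id == "s3"] <- rq2$rq[rq2$sample_id == "s3"] * 37
  res2 <- computeCNRQ(rq2, c("r1", "r2"), "CAL")
  expect_equal(sampleQuantities(res2)$cnrq, sampleQuantities(res)$cnrq,
               tolerance = 1e-12)
})

test_that("error propagation adds squared relative SEs with 1/f^2 weights", {
  expect_equal(propagateSE(0, numeric(0), 0), 0)
  expect_equal(propagateSE(0.03, 0.04), 0.05)
  expect_equal(propagateSE(0, c(0.04, 0.04)), sqrt(2 * (0.04 / 2)^2))
  expect_error(propagateSE(-0.1), ">= 0")
})

test_that("fold changes and directions follow the calibrator convention", {
  rq <- rqTable(sample_id = rep(paste0("s", 1:4), each = 2L),
                group = rep(c("CAL", "CAL", "UP", "DN"), each = 2L),
                gene = rep(c("g", "ref"), 4L),
                rq = c(1, 1, 1, 1, 20, 1, 1 / 3.4, 1))
  res <- computeCNRQ(rq, "ref", "CAL")
  up <- groupFoldChange(res, "g", "UP")
  expect_equal(up$fold, 20)
  expect_equal(up$log10_fold, log10(20))
  expect_equal(up$direction, "up")
  dn <- groupFoldChange(res, "g", "DN")
  expect_equal(dn$fold, 1 / 3.4, tolerance = 1e-12)
  expect_equal(dn$direction, "down")
  same <- groupFoldChange(res, "g", "CAL")
  expect_equal(same$log10_fold, 0)
  expect_equal(same$direction, "none")
  expect_error(groupFoldChange(res, "g", "NOPE"), "no results")
})

test_that("the Welch test is null on identical groups, powered on real shifts", {
  rq <- rqTable(sample_id = paste0("s", 1:6),
                group = rep(c("A", "B"), each = 3L),
                gene = "g", rq = c(2, 4, 8, 2, 4, 8))
  rq$rq_rel_se <- 0
  # normalise against itself so CNRQ spread stays within groups
  rq2 <- rbind(rq, rqTable(paste0("s", 1:6), rep(c("A", "B"), each = 3L),
                           "ref", 1))
  res <- computeCNRQ(rq2, "ref", "A")
  expect_equal(testDifferential(res, "g", "A", "B"), 1)

  sim <- simulateCq(cqSpec(bio_sd = 0.3, tech_sd = 0.3, seed = 504L))
  rqs <- relativeQuantities(sim$table, sim$truth$efficiencies)
  ress <- computeCNRQ(rqs, c("ref1", "ref2"), "A72")
  expect_lt(testDifferential(ress, "tgt1", "B72", "A72"), 0.01)
  expect_error(testDifferential(ress, "tgt1", "B72", "NOPE"), "2 biological")
})
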