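test_that("identical seed and config give identical output", {
  a <- simulateReplicateSet(simulationConfig(seed = 5),
                            consensusMode = "variant")
  b <- simulateReplicateSet(simulationConfig(seed = 5),
                            consensusMode = "variant")
  expect_identical(lapply(callSets(a$replicateSet), variantCalls),
                   lapply(callSets(b$replicateSet), variantCalls))
  expect_identical(a$truth, b$truth)
  c2 <- simulateReplicateSet(simulationConfig(seed = 6),
                             consensusMode = "variant")
  expect_false(identical(a$truth, c2$truth))
})

test_that("truth is conserved: emitted plus dropped equals configured", {
  sim <- simulateReplicateSet(simulationConfig(seed = 12,
                                               nTrueVariants = 300L),
                              consensusMode = "variant")
  tr <- sim$truth
  expect_equal(nrow(tr), 300L)
  expect_equal(sum(tr$n_replicates_emitted >= 1) +
               sum(tr$n_replicates_emitted == 0), 300L)
  # every emitted true variant appears in the replicate that emitted it;
  # false calls never appear in the truth table
  for (cs in callSets(sim$replicateSet)) {
    v <- variantCalls(cs)
    isTrue <- v$pos %in% tr$pos
    expect_true(all(tr$pos[tr$n_replicates_emitted ==
                           length(callSets(sim$replicateSet))] %in% v$pos))
    expect_gt(sum(!isTrue), 0)       # some false calls exist
    expect_false(any(v$pos[!isTrue] %in% tr$pos))
  }
})

test_that("no-noise duplicate call sets are fully concordant", {
  cfg <- simulationConfig(seed = 30, nTrueVariants = 200L,
                          errorRatePerBp = 0, coverageMean = 300,
                          coverageSize = 50,
                          detection = list(enabled = FALSE, minVac = 0L,
                                           errorP = 0.01, alpha = 1))
  sim <- simulateReplicateSet(cfg, consensusMode = "variant")
  expect_equal(concordanceRate(replicateConcordance(sim$replicateSet)), 1)
})

test_that("Rc matches the closed-form expectation without dropout", {
  # 1000 shared true variants + ~300 independent false calls per replicate
  # gives E[Rc] ~ 1000/1300 = 0.769
  rates <- vapply(1:5, function(s) {
    cfg <- simulationConfig(seed = 200 + s, nTrueVariants = 1000L,
                            errorRatePerBp = 300 / 50000,
                            detection = list(enabled = FALSE, minVac = 0L,
                                             errorP = 0.01, alpha = 1))
    sim <- simulateReplicateSet(cfg, consensusMode = "variant")
    concordanceRate(replicateConcordance(sim$replicateSet))
  }, 1)
  # three binomial sds of Nc/1300 around the expectation
  expect_true(all(abs(rates - 1000 / 1300) <
                  3 * sqrt(0.769 * 0.231 / 1300) + 0.02))
})

test_that("emitted VAF is bimodal: global mode near 1, second near 0.5", {
  sim <- simulateReplicateSet(simulationConfig(seed = 3),
                              consensusMode = "variant")
  v <- variantCalls(callSets(sim$replicateSet)[[1]])
  tr <- v[v$pos %in% sim$truth$pos, ]
  h <- hist(tr$vaf, breaks = seq(0, 1, 0.1), plot = FALSE)
  expect_equal(which.max(h$counts), 10L)        # top bin is the mode
  mids <- h$counts[4:7]                          # neighbourhood of 0.5
  expect_gt(max(mids), max(h$counts[8:9]))       # a secondary mode at ~0.5
  expect_lt(max(mids), h$counts[10])             # but much lower than 1.0
})

test_that("GC-rich windows get proportionally lower coverage", {
  cfg <- simulationConfig(seed = 17)
  sim <- simulateReplicateSet(cfg, consensusMode = "full")
  cn <- consensusCalls(callSets(sim$replicateSet)[[1]])
  gc <- gcAt(sim$gcTrack, cn$chrom, cn$pos)
  ratio <- mean(cn$coverage[gc >= 0.5]) / mean(cn$coverage[gc < 0.5])
  expect_lt(abs(ratio - cfg@gcEffect) / cfg@gcEffect, 0.10)
})

test_that("confident calls carry the configured p-value mass at zero", {
  sim <- simulateReplicateSet(simulationConfig(seed = 23,
                                               nTrueVariants = 800L),
                              consensusMode = "variant")
  v <- do.call(rbind, lapply(callSets(sim$replicateSet), variantCalls))
  conf <- v$pvalue[v$vac >= 10]
  expect_gt(length(conf), 500)
  expect_lt(abs(mean(conf == 0) - 0.91), 0.04)
  expect_true(all(v$pvalue[v$vac < 10] > 0))
})

test_that("batch scale shifts mean coverage proportionally", {
  mkCfg <- function(seed, scale)
    simulationConfig(seed = seed, nTargetBp = 15000L, batchScale = scale)
  cfgs <- c(lapply(41:43, mkCfg, scale = 1),
            lapply(44:46, mkCfg, scale = 2))
  sims <- simulateBatches(cfgs,
                          batchIds = rep(c("b1", "b2"), each = 3),
                          consensusMode = "full")
  # batch mean over samples and replicates averages out per-replicate
  # total-read variation, leaving the configured batch factor
  batchMean <- function(ix) mean(vapply(sims[ix], function(s)
    mean(vapply(callSets(s$replicateSet), function(cs)
      mean(consensusCalls(cs)$coverage), 1)), 1))
  ratio <- batchMean(4:6) / batchMean(1:3)
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.5)
  expect_equal(batchIds(sims[[1]]$replicateSet), rep("b1", 2))
  expect_error(simulateBatches(cfgs[1]), "at least 2")
})

test_that("replicate coverage correlates positively but imperfectly", {
  sim <- simulateReplicateSet(simulationConfig(seed = 19),
                              consensusMode = "full")
  cs <- callSets(sim$replicateSet)
  r <- coverageCorrelation(cs[[1]], cs[[2]])
  expect_gt(r, 0.2)
  expect_lt(r, 0.95)
})

test_that("pipeline recovers the planted structure from simulated data", {
  sim <- simulateReplicateSet(simulationConfig(seed = 55,
                                               nTrueVariants = 900L),
                              consensusMode = "variant")
  pooled <- poolStatus(sim$replicateSet)
  expect_gt(nrow(pooled), 1000)
  # reproduced group has higher coverage, VAC, VAF, VAQ
  for (f in c("coverage", "vac", "vaf", "vaq")) {
    g <- groupDifferenceTest(pooled, f)
    expect_gt(g$mean1, g$mean0)
    expect_lt(g$pvalue, 0.01)
  }
  # concordance rises with coverage: low-depth bins, where detection
  # dropout and low-VAC errors live, discord more than high-depth bins
  cs <- callSets(sim$replicateSet)
  tab <- concordanceByFactor(cs[[1]], cs[[2]], empiricalCoverageBins())
  expect_gt(tab$rate[tab$bin == "80-199x"], tab$rate[tab$bin == "5-19x"])
})

test_that("degenerate configs are rejected", {
  expect_error(simulationConfig(nTrueVariants = 0L, errorRatePerBp = 0),
               "degenerate")
  expect_error(simulationConfig(nReplicates = 4L), "2 or 3")
  expect_error(simulationConfig(vafWeights = c(0.5, 0.2, 0.2)), "sum to 1")
})
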