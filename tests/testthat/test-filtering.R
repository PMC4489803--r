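test_that("filter presets carry the reference thresholds", {
  pp <- pooledPreset()
  expect_equal(c(pp@minCoverage, pp@minVac, pp@minVaf, pp@minVaq),
               c(78, 45, 0.6, 22))
  cc <- categorizedCriteria()
  expect_equal(c(cc@minCoverage, cc@minVac, cc@minVaf, cc@minVaq),
               c(20, 20, 0.3, 20))
  expect_true(validObject(cc))
  # categorized is field-wise weaker, so it always keeps a superset
  expect_true(cc@minCoverage <= pp@minCoverage &&
              cc@minVac <= pp@minVac &&
              cc@minVaf <= pp@minVaf && cc@minVaq <= pp@minVaq)
})

test_that("pooled criteria are the reproduced-group means, rounded", {
  tab <- data.frame(status = c(1, 1, 1, 0, 0),
                    coverage = c(70, 80, 85.2, 10, 12),
                    vac = c(40, 45, 50, 2, 3),
                    vaf = c(0.55, 0.60, 0.62, 0.1, 0.1),
                    vaq = c(21, 22, 23.5, 8, 9),
                    pvalue = 0)
  crit <- pooledCriteria(tab)
  expect_equal(crit@minCoverage, round(mean(c(70, 80, 85.2))))
  expect_equal(crit@minVac, 45)
  expect_equal(crit@minVaf, 0.6)
  expect_equal(crit@minVaq, 22)
  # identical reproduced values give exactly those values
  tabSame <- data.frame(status = 1, coverage = 50, vac = 20, vaf = 0.5,
                        vaq = 30, pvalue = 0)[rep(1, 4), ]
  cs <- pooledCriteria(tabSame)
  expect_equal(c(cs@minCoverage, cs@minVac, cs@minVaf, cs@minVaq),
               c(50, 20, 0.5, 30))
  expect_error(pooledCriteria(data.frame(status = 0, coverage = 1,
                                         vac = 1, vaf = 0.1, vaq = 1,
                                         pvalue = 0)),
               "no reproduced")
})

test_that("each exclusion is attributable to exactly one rule on the toy", {
  cs <- makeCallSet("s", "r1", 1:5, "AG",
                    coverage = c(100L, 100L, 19L, 100L, 100L),
                    vac = c(50L, 50L, 15L, 8L, 50L),
                    vaf = c(0.8, 0.8, 0.8, 0.8, 0.2),
                    vaq = c(25, 10, 25, 25, 25))
  # only the first variant survives the categorized preset
  expect_equal(variantCalls(applyFilter(cs, categorizedCriteria()))$pos, 1L)
  # distinct thresholds make each exclusion attributable to one rule
  crit <- FilterCriteria(minCoverage = 20, minVac = 10, minVaf = 0.3,
                         minVaq = 20)
  out <- applyFilter(cs, crit)
  expect_equal(variantCalls(out)$pos, 1L)
  removed <- out@metadata$filterRemoved
  expect_equal(removed$coverage, 1L)        # only position 3 fails coverage
  expect_equal(removed$vaq, 1L)             # position 2
  expect_equal(removed$vac, 1L)             # position 4
  expect_equal(removed$vaf, 1L)             # position 5
  # removed + retained = input
  expect_equal(nrow(variantCalls(out)) +
               sum(unlist(removed[c("coverage", "vac", "vaf", "vaq")])),
               nrow(variantCalls(cs)))
})

test_that("filtering is idempotent and the empty criteria are identity", {
  sim <- simulateReplicateSet(simulationConfig(seed = 4),
                              consensusMode = "variant")
  cs <- callSets(sim$replicateSet)[[1]]
  once <- applyFilter(cs, categorizedCriteria())
  twice <- applyFilter(once, categorizedCriteria())
  expect_equal(variantCalls(once), variantCalls(twice))
  ident <- applyFilter(cs, FilterCriteria())
  expect_equal(variantCalls(ident), variantCalls(cs))
})

test_that("stricter criteria keep a subset of weaker criteria's survivors", {
  sim <- simulateReplicateSet(simulationConfig(seed = 8),
                              consensusMode = "variant")
  cs <- callSets(sim$replicateSet)[[1]]
  weak <- variantCalls(applyFilter(cs, categorizedCriteria()))
  strict <- variantCalls(applyFilter(cs, pooledPreset()))
  expect_true(all(paste(strict$chrom, strict$pos) %in%
                  paste(weak$chrom, weak$pos)))
})

test_that("pair coverage floor removes positions failing on either side", {
  a <- makeCallSet("s", "r1", 1:3, "AG", coverage = c(25L, 25L, 18L))
  b <- makeCallSet("s", "r2", 1:3, "AG", coverage = c(18L, 30L, 40L))
  out <- coverageFilterPair(a, b, minCoverage = 20)
  expect_equal(variantCalls(out$a)$pos, 2L)   # 25/18 and 18/40 removed
  expect_equal(variantCalls(out$b)$pos, 2L)
  allHigh <- coverageFilterPair(b, b, minCoverage = 10)
  expect_equal(variantCalls(allHigh$a), variantCalls(b))
})

test_that("coverage filtering raises Rc when low-coverage calls discord", {
  # concordant at high coverage, discordant only at low coverage
  a <- makeCallSet("s", "r1", 1:6, c(rep("AG", 4), "AC", "AT"),
                   coverage = c(50L, 50L, 50L, 50L, 10L, 12L))
  b <- makeCallSet("s", "r2", 1:6, c(rep("AG", 4), "AG", "AG"),
                   coverage = c(60L, 60L, 60L, 60L, 11L, 13L))
  before <- concordanceRate(snvConcordance(a, b))
  f <- coverageFilterPair(a, b, minCoverage = 20)
  after <- concordanceRate(snvConcordance(f$a, f$b))
  expect_gt(after, before)
  expect_equal(after, 1)
})

test_that("filter effect summarises before/after with a paired test", {
  # identity criteria: no change, flagged as no-difference
  sets <- lapply(1:3, function(s)
    simulateReplicateSet(simulationConfig(seed = s, nTargetBp = 10000L,
                                          nTrueVariants = 100L),
                         consensusMode = "variant")$replicateSet)
  eff0 <- filterEffect(sets, FilterCriteria())
  expect_true(eff0$noDifference)
  expect_true(is.na(eff0$pvalue))
  expect_equal(eff0$meanBefore, eff0$meanAfter)
  # mean/sd across pairs equal hand computation
  effC <- filterEffect(sets, categorizedCriteria())
  expect_equal(effC$meanBefore, mean(effC$perSet$rate_before))
  expect_equal(effC$sdAfter, sd(effC$perSet$rate_after))
  expect_error(filterEffect(sets[1], categorizedCriteria()), "at least 2")
})

test_that("low-VAC/VAF error calls make the categorized preset help", {
  set.seed(99)
  sets <- lapply(1:4, function(s)
    simulateReplicateSet(
      simulationConfig(seed = 100 + s, nTargetBp = 20000L,
                       nTrueVariants = 300L,
                       errorRatePerBp = 90 / 20000),
      consensusMode = "variant")$replicateSet)
  eff <- filterEffect(sets, categorizedCriteria())
  expect_gt(eff$meanAfter, eff$meanBefore)
})
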