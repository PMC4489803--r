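test_that("pooled status table covers the union of called positions", {
  a <- makeCallSet("s", "r1", c(1, 2, 3), c("AG", "AC", "AT"))
  b <- makeCallSet("s", "r2", c(1, 2, 4, 5), c("AG", "AG", "AT", "AC"))
  tab <- poolStatus(ReplicateSet(list(a, b)))
  expect_equal(nrow(tab), 3 + 4 - 2)       # N1 + N2 - shared
  expect_equal(sum(tab$status), 1)         # only pos 1 concordant

  ident <- makeCallSet("s", "r1", 1:10, "AG")
  tab2 <- poolStatus(ReplicateSet(list(ident, ident)))
  expect_equal(nrow(tab2), 10L)
  expect_true(all(tab2$status == 1))

  d1 <- makeCallSet("s", "r1", 1:3, "AG")
  d2 <- makeCallSet("s", "r2", 11:14, "AG")
  tab3 <- poolStatus(ReplicateSet(list(d1, d2)))
  expect_equal(nrow(tab3), 7L)
  expect_true(all(tab3$status == 0))
})

test_that("pair factor values are replicate means, consensus fills gaps", {
  a <- makeCallSet("s", "r1", 1:2, "AG", coverage = c(100L, 60L))
  cons <- data.frame(chrom = "chr1", pos = 1:3, ref = "A", call = "A",
                     coverage = c(80L, 40L, 20L), vac = 0L, vaf = 0,
                     vaq = NA_real_, pvalue = NA_real_)
  b <- CallSet("s", "r2",
               variants = variantCalls(makeCallSet("s", "rx", 1L, "AG",
                                                   coverage = 120L)),
               consensus = cons)
  tab <- poolStatus(ReplicateSet(list(a, b)))
  tab <- tab[order(tab$pos), ]
  expect_equal(tab$coverage, c(mean(c(100, 120)), mean(c(60, 40))))
})

test_that("group comparison detects shifted factors and not null ones", {
  set.seed(11)
  tab <- data.frame(status = rep(c(1, 0), each = 500),
                    same = rnorm(1000),
                    shifted = c(rnorm(500, 2), rnorm(500)))
  nullRes <- groupDifferenceTest(tab, "same")
  expect_gt(nullRes$pvalue, 0.05)
  shiftRes <- groupDifferenceTest(tab, "shifted")
  expect_lt(shiftRes$pvalue, 1e-10)
  expect_gt(shiftRes$mean1, shiftRes$mean0)
  expect_equal(shiftRes$n1, 500L)
  tiny <- data.frame(status = c(1, 0, 0), x = c(1, 2, 3))
  expect_error(groupDifferenceTest(tiny, "x"), "at least 2")
})

test_that("factor R2 spans 0 (no between) to 1 (no within)", {
  same <- data.frame(bin = rep(c("a", "b"), each = 3),
                     rate = rep(c(0.5, 0.7, 0.9), 2))
  expect_equal(factorR2(same)$r2, 0)
  pure <- data.frame(bin = rep(c("a", "b"), each = 3),
                     rate = rep(c(0.4, 0.8), each = 3))
  expect_equal(factorR2(pure)$r2, 1)
  # hand ANOVA on a 2-bin x 3-rate table
  df <- data.frame(bin = rep(c("a", "b"), each = 3),
                   rate = c(0.5, 0.6, 0.7, 0.8, 0.9, 1.0))
  gm <- mean(df$rate)
  ssb <- 3 * ((mean(df$rate[1:3]) - gm)^2 + (mean(df$rate[4:6]) - gm)^2)
  sst <- sum((df$rate - gm)^2)
  expect_equal(factorR2(df)$r2, ssb / sst)
  expect_error(factorR2(data.frame(bin = "a", rate = c(0.1, 0.2))),
               "2 bins")
  # affine rescaling of the factor leaves bins, hence R2, unchanged:
  # the statistic only sees bin labels, asserted by label permutation
  df2 <- df
  df2$bin <- c("b", "b", "b", "a", "a", "a")
  expect_equal(factorR2(df2)$r2, factorR2(df)$r2)
})

test_that("mutual information matches analytic values", {
  # independence
  expect_equal(mutualInformationFromCounts(matrix(c(25, 25, 25, 25), 2)), 0)
  expect_equal(mutualInformationFromCounts(matrix(c(30, 60, 10, 20), 2)), 0)
  # perfect prediction of a balanced status: MI = H(status) = ln 2
  expect_equal(mutualInformationFromCounts(matrix(c(50, 0, 0, 50), 2)),
               log(2))
  # hand-computed plug-in value for [[30,10],[10,30]]
  hand <- 2 * (0.375 * log(0.375 / 0.25) + 0.125 * log(0.125 / 0.25))
  expect_equal(mutualInformationFromCounts(matrix(c(30, 10, 10, 30), 2)),
               hand)
  expect_error(mutualInformationFromCounts(matrix(0, 2, 2)), "empty")
})

test_that("MI through a bin scheme is label-invariant and non-negative", {
  set.seed(3)
  tab <- data.frame(status = rbinom(400, 1, 0.5), x = runif(400, 0, 100))
  sc <- sturgesBins(tab$x, factorName = "x")
  res <- mutualInformation(tab, "x", sc)
  expect_gte(res$mi, 0)
  expect_equal(res$mi_bits, res$mi / log(2))
  # permuting bin labels (reversing the edge orientation via -x) keeps MI
  tab2 <- tab
  tab2$x <- -tab$x
  sc2 <- sturgesBins(tab2$x, factorName = "x")
  expect_equal(mutualInformation(tab2, "x", sc2)$mi, res$mi,
               tolerance = 1e-12)
})

test_that("univariate logistic AIC matches the intercept-only closed form", {
  tab <- data.frame(status = rep(c(0, 1), 50), x = rep(1, 100))
  aic <- univariateAic(tab, "x")
  expect_equal(aic, 2 * 2 - 2 * 100 * log(0.5), tolerance = 1e-8)
  # affine invariance
  set.seed(9)
  tab2 <- data.frame(status = rbinom(300, 1, 0.5), x = rnorm(300))
  tab2$xa <- 3 * tab2$x - 7
  expect_equal(univariateAic(tab2, "x"), univariateAic(tab2, "xa"),
               tolerance = 1e-6)
})

test_that("AIC ranks a true driver above its permuted copy", {
  set.seed(21)
  ok <- 0L
  for (i in 1:10) {
    n <- 2000
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(1.5 * x))
    tab <- data.frame(status = y, x = x, xperm = sample(x))
    if (univariateAic(tab, "x") < univariateAic(tab, "xperm"))
      ok <- ok + 1L
  }
  expect_gte(ok, 10L * 0.95)
})

test_that("stronger simulated effects give smaller AIC", {
  set.seed(33)
  deltas <- replicate(20, {
    n <- 1000
    x <- rnorm(n)
    yw <- rbinom(n, 1, plogis(0.3 * x))
    ys <- rbinom(n, 1, plogis(2.0 * x))
    univariateAic(data.frame(status = ys, x = x), "x") -
      univariateAic(data.frame(status = yw, x = x), "x")
  })
  expect_true(all(deltas < 0))
})

test_that("lasso entry order finds the driving factor first", {
  set.seed(14)
  hits <- 0L
  for (i in 1:5) {
    n <- 2000
    z <- matrix(rnorm(n * 5), n, 5,
                dimnames = list(NULL, paste0("z", 1:5)))
    y <- rbinom(n, 1, plogis(3 * z[, 1]))
    tab <- data.frame(status = y, z)
    ord <- lassoEntryOrder(tab, paste0("z", 1:5))
    if (ord$factor[1] == "z1" && ord$entry_rank[1] == 1 && !ord$tied[1])
      hits <- hits + 1L
  }
  expect_equal(hits, 5L)
})

test_that("lasso path reports duplicates as ties and supports exclusion", {
  set.seed(42)
  n <- 500
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- rbinom(n, 1, plogis(2 * x1 + 0.5 * x2))
  tab <- data.frame(status = y, a = x1, acopy = x1, b = x2)
  ord <- lassoEntryOrder(tab, c("a", "acopy", "b"))
  expect_true(all(ord$tied[ord$factor %in% c("a", "acopy")]))
  expect_equal(ord$entry_lambda[ord$factor == "a"],
               ord$entry_lambda[ord$factor == "acopy"])
  # no coefficient is active at lambda_max itself
  expect_true(all(ord$entry_lambda < max(ord$entry_lambda) * 1.0001))
  # excluding the dominant factor re-runs the race without it
  ord2 <- lassoEntryOrder(tab, c("a", "acopy", "b"), exclude = "a")
  expect_false("a" %in% ord2$factor)
  expect_error(lassoEntryOrder(tab, "a"), "at least 2")
})

test_that("association summary combines MI, AIC, and lasso coherently", {
  sim <- simulateReplicateSet(simulationConfig(seed = 2),
                              consensusMode = "variant")
  pooled <- poolStatus(sim$replicateSet)
  schemes <- buildFactorSchemes(pooled)
  summ <- suppressWarnings(associationSummary(pooled, schemes))
  expect_setequal(summ$factor,
                  c("coverage", "vac", "vaf", "vaq", "pvalue"))
  expect_true(all(summ$mutual_information >= 0))
  # the three measures agree that a true driver (vac or vaf) leads
  expect_true(summ$factor[which.max(summ$mutual_information)] %in%
              c("vac", "vaf"))
  expect_true(summ$factor[which.min(summ$aic)] %in% c("vac", "vaf"))
  first <- summ$factor[!is.na(summ$lasso_entry_rank) &
                       summ$lasso_entry_rank == 1]
  expect_true(any(first %in% c("vac", "vaf")))
})
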