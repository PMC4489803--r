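#' @include binning.R
NULL

#' Pool SNV calls of all replicate pairs into a concordance-status table
#'
#' Every SNV position of every pair (called in at least one replicate) gets
#' one row with status 1 (concordant: called in both with identical
#' genotype) or 0 (discordant), together with its factor values. The factor
#' value of a pair is the mean of the two replicates' values at the
#' position; where one replicate has no variant call its consensus-table
#' value supplies its side.
#'
#' @param repSets list of [ReplicateSet-class] objects (or a single one).
#' @return data.frame with columns sample_id, pair_id, chrom, pos, status,
#'   coverage, vac, vaf, vaq, pvalue.
#' @export
poolStatus <- function(repSets) {
  if (is(repSets, "ReplicateSet")) repSets <- list(repSets)
  numFactors <- c("coverage", "vac", "vaf", "vaq", "pvalue")
  rows <- list()
  for (rs in repSets) {
    cs <- callSets(rs)
    idx <- utils::combn(length(cs), 2L)
    for (j in seq_len(ncol(idx))) {
      a <- cs[[idx[1, j]]]
      b <- cs[[idx[2, j]]]
      va <- variantCalls(a)
      vb <- variantCalls(b)
      ka <- paste(va$chrom, va$pos)
      kb <- paste(vb$chrom, vb$pos)
      keys <- union(ka, kb)
      gA <- va$genotype[match(keys, ka)]
      gB <- vb$genotype[match(keys, kb)]
      status <- as.integer(!is.na(gA) & !is.na(gB) & gA == gB)
      tab <- data.frame(
        sample_id = sampleId(rs),
        pair_id = sprintf("%s:%d-%d", sampleId(rs), idx[1, j], idx[2, j]),
        chrom = sub(" [0-9]+$", "", keys),
        pos = as.integer(sub("^.* ", "", keys)),
        status = status, stringsAsFactors = FALSE)
      for (f in numFactors) {
        fa <- .factorValuesAt(a, keys, f)
        fb <- .factorValuesAt(b, keys, f)
        tab[[f]] <- rowMeans(cbind(fa, fb), na.rm = TRUE)
      }
      rows[[length(rows) + 1L]] <- tab
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare factor values between reproduced and not-reproduced calls
#'
#' Group means, standard deviations, and a two-sided two-sample t-test for
#' one factor between the status = 1 (reproduced) and status = 0
#' (not-reproduced) groups of a pooled status table.
#'
#' @param table a pooled status table from [poolStatus()].
#' @param factorName one of coverage, vac, vaf, vaq, pvalue.
#' @return list with mean1, sd1, n1 (reproduced), mean0, sd0, n0
#'   (not-reproduced) and pvalue.
#' @export
groupDifferenceTest <- function(table, factorName) {
  x1 <- table[[factorName]][table$status == 1]
  x0 <- table[[factorName]][table$status == 0]
  x1 <- x1[!is.na(x1)]; x0 <- x0[!is.na(x0)]
  if (length(x1) < 2L || length(x0) < 2L)
    stop("both status groups need at least 2 observations")
  p <- if (stats::sd(x1) == 0 && stats::sd(x0) == 0) {
    if (mean(x1) == mean(x0)) 1 else 0
  } else stats::t.test(x1, x0, alternative = "two.sided")$p.value
  list(mean1 = mean(x1), sd1 = stats::sd(x1), n1 = length(x1),
       mean0 = mean(x0), sd0 = stats::sd(x0), n0 = length(x0),
       pvalue = p)
}

#' Proportion of concordance-rate variation explained by one factor
#'
#' One-way ANOVA of the per-pair per-bin concordance rates grouped by bin:
#' \eqn{R^2 = SS_{between}/SS_{total}}, with the ANOVA p-value.
#'
#' @param stratified a [StratifiedConcordance-class] over all pairs (from
#'   [stratifyReplicateSets()]), or a data.frame with columns \code{bin}
#'   and \code{rate}.
#' @return list with r2 and pvalue.
#' @export
factorR2 <- function(stratified) {
  df <- if (is(stratified, "StratifiedConcordance")) stratified@perPair
        else stratified
  df <- df[!is.na(df$rate), , drop = FALSE]
  df$bin <- factor(df$bin)
  df <- droplevels(df)
  if (nlevels(df$bin) < 2L)
    stop("need rates in at least 2 bins")
  fit <- stats::aov(rate ~ bin, data = df)
  an <- summary(fit)[[1]]
  ssb <- an["bin", "Sum Sq"]
  sst <- sum(an[, "Sum Sq"])
  list(r2 = if (sst > 0) ssb / sst else 0,
       pvalue = an["bin", "Pr(>F)"])
}

#' Mutual information from a joint count table
#'
#' Plug-in estimate \eqn{I = \sum_{s,b} p(s,b)\,\ln\frac{p(s,b)}{p(s)p(b)}}
#' in nats, with \eqn{0 \ln 0 := 0}.
#'
#' @param counts matrix of joint counts (rows = one variable's levels,
#'   columns = the other's).
#' @return mutual information in nats.
#' @export
mutualInformationFromCounts <- function(counts) {
  counts <- as.matrix(counts)
  n <- sum(counts)
  if (n == 0) stop("empty count table")
  p <- counts / n
  ps <- rowSums(p)
  pb <- colSums(p)
  mi <- 0
  for (i in seq_along(ps)) for (j in seq_along(pb)) {
    if (p[i, j] > 0)
      mi <- mi + p[i, j] * log(p[i, j] / (ps[i] * pb[j]))
  }
  max(mi, 0)
}

#' Mutual information between a binned factor and concordance status
#'
#' The factor is discretised with the same bin scheme used for stratified
#' concordance; rows with out-of-range or missing values are dropped.
#'
#' @param table a pooled status table from [poolStatus()].
#' @param factorName factor column to bin.
#' @param scheme the [BinScheme-class] for the factor.
#' @return list with mi (nats) and mi_bits.
#' @export
mutualInformation <- function(table, factorName, scheme) {
  if (!nrow(table)) stop("empty status table")
  bins <- binAssign(scheme, table[[factorName]])
  keep <- !is.na(bins)
  counts <- table(status = table$status[keep], bin = droplevels(bins[keep]))
  mi <- mutualInformationFromCounts(counts)
  list(mi = mi, mi_bits = mi / log(2))
}

#' AIC of the univariate logistic regression status ~ factor
#'
#' Fits \eqn{\mathrm{logit}\,P(\mathrm{status}=1) = \beta_0 + \beta_1 x} by
#' maximum likelihood and returns \eqn{AIC = 2k - 2\ln\hat L} with
#' \eqn{k = 2}. Smaller is better. Perfect separation is flagged with a
#' warning; the AIC from the iteration-limited fit is still returned.
#'
#' @param table a pooled status table from [poolStatus()].
#' @param factorName continuous factor column.
#' @return the AIC (numeric).
#' @export
univariateAic <- function(table, factorName) {
  x <- table[[factorName]]
  y <- table$status
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(unique(y)) < 2L)
    stop("both status classes must be present")
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep)
    warning("possible complete separation for factor '", factorName,
            "'; AIC from the iteration-limited fit")
  # the univariate model always charges k = 2 (intercept + slope), also
  # when a degenerate factor leaves the slope inestimable
  2 * 2 - 2 * as.numeric(stats::logLik(fit))
}

#' Entry order of factors along the L1-penalised logistic path
#'
#' Computes the lasso (L1-penalised logistic regression) regularisation
#' path over a decreasing grid of penalties from \eqn{\lambda_{max}} (all
#' coefficients zero) downward and records the penalty at which each
#' factor's coefficient first becomes nonzero. The most strongly associated
#' factor enters the model first. Predictors are standardised to unit
#' variance before fitting. Factors entering at the same grid point are
#' reported as a tie (equal rank), never silently broken.
#'
#' @param table a pooled status table from [poolStatus()].
#' @param factorNames continuous factor columns to race (>= 2).
#' @param exclude factors to leave out before fitting (e.g. re-run without
#'   the dominant one).
#' @param nlambda,lambdaMinRatio grid: \code{nlambda} log-spaced penalties
#'   down to \code{lambdaMinRatio * lambda_max}.
#' @return data.frame ordered by entry: factor, entry_rank (ties share the
#'   smallest rank), entry_lambda (NA if the factor never enters), tied
#'   (logical).
#' @export
lassoEntryOrder <- function(table, factorNames, exclude = NULL,
                            nlambda = 100L, lambdaMinRatio = 0.001) {
  factorNames <- setdiff(factorNames, exclude)
  if (length(factorNames) < 2L)
    stop("need at least 2 factors")
  keep <- stats::complete.cases(table[factorNames]) & !is.na(table$status)
  x <- as.matrix(table[keep, factorNames])
  y <- table$status[keep]
  if (length(unique(y)) < 2L)
    stop("both status classes must be present")
  # perfectly collinear predictors share the same entry penalty by the KKT
  # condition; coordinate descent would pick one arbitrarily, so collapse
  # them to one representative and report the group as a tie
  cm <- suppressWarnings(stats::cor(x))
  cm[!is.finite(cm)] <- 0
  groupOf <- seq_along(factorNames)
  for (j in seq_along(factorNames)) {
    dup <- which(abs(abs(cm[j, seq_len(j - 1L)]) - 1) < 1e-12)
    if (length(dup)) groupOf[j] <- groupOf[dup[1]]
  }
  repCols <- match(unique(groupOf), groupOf)
  fit <- glmnet::glmnet(x[, repCols, drop = FALSE], y,
                        family = "binomial", alpha = 1,
                        standardize = TRUE, nlambda = nlambda,
                        lambda.min.ratio = lambdaMinRatio)
  beta <- as.matrix(fit$beta)
  entryIdxRep <- apply(beta != 0, 1L, function(r)
    if (any(r)) which(r)[1] else NA_integer_)
  entryIdx <- entryIdxRep[match(groupOf, unique(groupOf))]
  entryLambda <- fit$lambda[entryIdx]
  rk <- rank(entryIdx, ties.method = "min", na.last = "keep")
  out <- data.frame(factor = factorNames,
                    entry_rank = rk,
                    entry_lambda = entryLambda,
                    stringsAsFactors = FALSE)
  out$tied <- !is.na(out$entry_rank) &
    out$entry_rank %in% out$entry_rank[duplicated(out$entry_rank)]
  out[order(out$entry_rank, na.last = TRUE), , drop = FALSE]
}

#' Per-factor association summary: MI, AIC and lasso entry rank
#'
#' One row per factor combining the three importance measures computed on a
#' pooled status table: mutual information against the factor's bin scheme,
#' the univariate-logistic AIC, and the rank at which the factor enters the
#' L1 path.
#'
#' @param table a pooled status table from [poolStatus()].
#' @param schemes named list of [BinScheme-class] objects, one per factor;
#'   the names define the factor set.
#' @return data.frame: factor, mutual_information (nats), mi_bits, aic,
#'   lasso_entry_rank, lasso_entry_lambda.
#' @export
associationSummary <- function(table, schemes) {
  factors <- names(schemes)
  lasso <- lassoEntryOrder(table, factors)
  mi <- vapply(factors, function(f)
    mutualInformation(table, f, schemes[[f]])$mi, 1)
  aic <- vapply(factors, function(f) univariateAic(table, f), 1)
  data.frame(factor = factors,
             mutual_information = mi,
             mi_bits = mi / log(2),
             aic = aic,
             lasso_entry_rank = lasso$entry_rank[match(factors,
                                                       lasso$factor)],
             lasso_entry_lambda = lasso$entry_lambda[match(factors,
                                                           lasso$factor)],
             row.names = NULL, stringsAsFactors = FALSE)
}
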