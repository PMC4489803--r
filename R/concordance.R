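#' @include utils.R
NULL

.concordanceResult <- function(nc, n1, n2, pairs = list()) {
  denom <- mean(c(n1, n2))
  if (denom == 0) stop("both call sets are empty: concordance rate undefined")
  new("ConcordanceResult", nConcordant = nc, nTotal1 = n1, nTotal2 = n2,
      rate = nc / denom, pairResults = pairs)
}

#' SNV-call concordance between two replicate call sets
#'
#' Computes the concordance rate
#' \deqn{R_c = \frac{N_c}{\mathrm{mean}(N_1, N_2)}}
#' where \eqn{N_c} is the number of positions called as an SNV in both
#' replicates with identical genotype (unordered allele-pair equality:
#' "genotype comparison"), and \eqn{N_1}, \eqn{N_2} are the per-replicate
#' SNV totals. A position called in only one replicate, or called in both
#' with differing genotypes, is discordant; the former counts toward that
#' replicate's total only.
#'
#' @param a,b [CallSet-class] objects from the same sample.
#' @return a [ConcordanceResult-class].
#' @examples
#' v <- data.frame(chrom = "chr1", pos = 1:3 * 10L, ref = "A",
#'                 genotype = "AG", variantAllele = "G")
#' cs <- CallSet("s", "r1", v)
#' concordanceRate(snvConcordance(cs, cs))  # identical sets: 1
#' @export
snvConcordance <- function(a, b) {
  stopifnot(is(a, "CallSet"), is(b, "CallSet"))
  if (!is.na(a@sampleId) && !is.na(b@sampleId) &&
      a@sampleId != b@sampleId)
    warning("comparing call sets from different samples: ",
            a@sampleId, " vs ", b@sampleId)
  va <- variantCalls(a)
  vb <- variantCalls(b)
  ka <- paste(va$chrom, va$pos)
  kb <- paste(vb$chrom, vb$pos)
  shared <- intersect(ka, kb)
  nc <- sum(va$genotype[match(shared, ka)] == vb$genotype[match(shared, kb)],
            na.rm = TRUE)
  .concordanceResult(nc, nrow(va), nrow(vb))
}

#' Concordance of a ReplicateSet (duplicate or triplicate)
#'
#' Duplicates give the single pairwise rate. For triplicates the three
#' pairwise rates are computed and their unweighted mean is the summary
#' rate; the per-pair results are kept in \code{pairResults}.
#'
#' @param reps a [ReplicateSet-class] (2 or 3 replicates).
#' @param statistic which call comparison to summarise: \code{"snv"}
#'   (default, genotype comparison of SNV calls) or \code{"allcall"}
#'   (consensus-table comparison via [allcallConcordance()]).
#' @param ... passed to [allcallConcordance()] when
#'   \code{statistic = "allcall"}.
#' @return a [ConcordanceResult-class]; for triplicates its counts are the
#'   means of the per-pair counts and \code{pairResults} holds the pairs.
#' @export
replicateConcordance <- function(reps, statistic = c("snv", "allcall"), ...) {
  stopifnot(is(reps, "ReplicateSet"))
  statistic <- match.arg(statistic)
  cs <- callSets(reps)
  if (length(cs) < 2L) stop("need at least 2 replicates")
  fun <- if (statistic == "snv") snvConcordance else allcallConcordance
  idx <- utils::combn(length(cs), 2L)
  pairs <- lapply(seq_len(ncol(idx)), function(j)
    fun(cs[[idx[1, j]]], cs[[idx[2, j]]], ...))
  if (length(pairs) == 1L) return(pairs[[1]])
  new("ConcordanceResult",
      nConcordant = mean(vapply(pairs, function(p) p@nConcordant, 1)),
      nTotal1 = mean(vapply(pairs, function(p) p@nTotal1, 1)),
      nTotal2 = mean(vapply(pairs, function(p) p@nTotal2, 1)),
      rate = mean(vapply(pairs, function(p) p@rate, 1)),
      pairResults = pairs)
}

#' Whole-region concordance over all nucleotide calls
#'
#' Compares the per-position consensus calls of two replicates over the
#' positions present in both tables. With \code{excludeAmbiguous = TRUE}
#' (the headline "unambiguous" statistic) every position where either call
#' is \code{N} is removed before comparison. With
#' \code{excludeAmbiguous = FALSE}, N-vs-base counts as discordant and
#' N-vs-N as concordant. Concordant means the identical call symbol;
#' \eqn{N_1 = N_2 =} the number of compared positions, so the rate is the
#' plain fraction concordant.
#'
#' @param a,b [CallSet-class] objects with consensus tables.
#' @param excludeAmbiguous drop positions where either call is N
#'   (default TRUE).
#' @return a [ConcordanceResult-class].
#' @export
allcallConcordance <- function(a, b, excludeAmbiguous = TRUE) {
  ca <- consensusCalls(a)
  cb <- consensusCalls(b)
  if (is.null(ca) || is.null(cb))
    stop("both call sets need consensus tables")
  ka <- paste(ca$chrom, ca$pos)
  kb <- paste(cb$chrom, cb$pos)
  shared <- intersect(ka, kb)
  if (!length(shared)) stop("no shared positions between consensus tables")
  callA <- ca$call[match(shared, ka)]
  callB <- cb$call[match(shared, kb)]
  if (excludeAmbiguous) {
    keep <- !is.na(callA) & !is.na(callB) & callA != "N" & callB != "N"
    if (!any(keep))
      stop("no unambiguous shared positions to compare")
    callA <- callA[keep]
    callB <- callB[keep]
  }
  n <- length(callA)
  nc <- sum(callA == callB, na.rm = TRUE)
  .concordanceResult(nc, n, n)
}

#' Pearson correlation of coverage depth between replicates
#'
#' Over all consensus positions with at least one read in both replicates.
#'
#' @param a,b [CallSet-class] objects with consensus tables carrying
#'   coverage.
#' @return Pearson correlation coefficient.
#' @export
coverageCorrelation <- function(a, b) {
  ca <- consensusCalls(a)
  cb <- consensusCalls(b)
  if (is.null(ca) || is.null(cb))
    stop("both call sets need consensus tables")
  ka <- paste(ca$chrom, ca$pos)
  kb <- paste(cb$chrom, cb$pos)
  shared <- intersect(ka, kb)
  x <- ca$coverage[match(shared, ka)]
  y <- cb$coverage[match(shared, kb)]
  keep <- !is.na(x) & !is.na(y) & x >= 1 & y >= 1
  if (sum(keep) < 3L)
    stop("fewer than 3 positions with coverage >= 1 in both replicates")
  stats::cor(x[keep], y[keep], method = "pearson")
}

#' Lin's concordance correlation coefficient
#'
#' \deqn{\rho_c = \frac{2\,\mathrm{cov}(x,y)}
#'   {\mathrm{var}(x)+\mathrm{var}(y)+(\bar x - \bar y)^2}}
#' with population (1/n) moments. Unlike Pearson's r it penalises location
#' and scale shifts, so \eqn{|\rho_c| \le |r|}.
#'
#' @param x,y equal-length paired numeric vectors.
#' @return numeric in [-1, 1].
#' @export
linCCC <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  mx <- mean(x); my <- mean(y)
  sxy <- mean((x - mx) * (y - my))
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

#' Spearman and concordance correlation of a paired sequencing metric
#'
#' Summarises the replicate-to-replicate agreement of one basic sequencing
#' metric (total reads, on-target fraction, mean coverage, ...) across
#' replicated samples.
#'
#' @param metricsA,metricsB paired metric vectors, one entry per sample.
#' @param metricName label carried into the result.
#' @return data.frame with metric_name, spearman_rho, lin_ccc.
#' @export
metricCorrelations <- function(metricsA, metricsB, metricName = "metric") {
  if (length(metricsA) != length(metricsB))
    stop("paired metric vectors must have equal length")
  if (length(metricsA) < 3L) stop("need at least 3 paired samples")
  data.frame(metric_name = metricName,
             spearman_rho = stats::cor(metricsA, metricsB,
                                       method = "spearman"),
             lin_ccc = linCCC(metricsA, metricsB),
             stringsAsFactors = FALSE)
}

#' Format a concordance rate as the conventionally printed percentage
#'
#' Percentages are rounded half-up: 1 decimal for SNV concordance, 4 for
#' whole-region (all-call) concordance.
#'
#' @param rate numeric rate in [0, 1].
#' @param digits decimals of the percentage (1 for SNV, 4 for all-call).
#' @return numeric percentage rounded half-up.
#' @export
percentRate <- function(rate, digits = 1) {
  scale <- 10^digits
  floor(rate * 100 * scale + 0.5) / scale
}
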