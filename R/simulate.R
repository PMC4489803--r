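#' @include utils.R
NULL

#' Build a SimulationConfig with study-like defaults
#'
#' The defaults emulate the statistical structure of replicated targeted
#' kinome capture sequencing, scaled to a 50 kb desk-size target: shared
#' true variants whose VAF distribution peaks near 1 with a much lower
#' secondary peak near 0.5 and a low-frequency tail; negative-binomial
#' per-position coverage with mean 116x in GC-low windows, depressed by
#' \code{gcEffect} (39/116) in GC-high windows and boosted by
#' \code{exonEffect} (65/44) in exonic blocks; independent per-replicate
#' false calls with VAC of 1--5 reads; 91\% of confident calls with SNV
#' p-value exactly 0; and per-replicate/batch variation in total reads.
#'
#' @param seed integer RNG seed for this simulated set.
#' @param nTargetBp target size in bp (>= 1000).
#' @param nTrueVariants shared true variants placed once per sample.
#' @param vafWeights weights of the near-1 peak, the near-0.5 peak, and the
#'   low-VAF tail (must sum to 1).
#' @param errorRatePerBp expected false SNV calls per bp per replicate.
#' @param coverageMean,coverageSize negative-binomial coverage model
#'   (GC-low baseline mean; size = dispersion).
#' @param gcEffect coverage multiplier for GC >= 50\% windows.
#' @param exonEffect coverage multiplier for exonic blocks.
#' @param pvalueZeroMass point mass at p = 0 for confident (VAC >= 10)
#'   calls.
#' @param nReplicates 2 (duplicate) or 3 (triplicate).
#' @param batchScale multiplicative total-read factor of the batch.
#' @param detection list(enabled, minVac, errorP, alpha): a true variant is
#'   emitted in a replicate only when its sampled VAC reaches \code{minVac}
#'   and a one-sided binomial test against per-read error rate
#'   \code{errorP} is below \code{alpha} — dropout is driven by coverage
#'   and VAC, not by an independent coin flip.
#' @return a validated [SimulationConfig-class].
#' @export
simulationConfig <- function(seed = 1L,
                             nTargetBp = 50000L,
                             nTrueVariants = 500L,
                             vafWeights = c(0.65, 0.20, 0.15),
                             errorRatePerBp = 0.003,
                             coverageMean = 116,
                             coverageSize = 2,
                             gcEffect = 39 / 116,
                             exonEffect = 65 / 44,
                             pvalueZeroMass = 0.91,
                             nReplicates = 2L,
                             batchScale = 1,
                             detection = list(enabled = TRUE, minVac = 2L,
                                              errorP = 0.01,
                                              alpha = 1e-6)) {
  new("SimulationConfig", seed = as.integer(seed),
      nTargetBp = as.integer(nTargetBp),
      nTrueVariants = as.integer(nTrueVariants),
      vafMixture = list(weights = vafWeights),
      errorRatePerBp = errorRatePerBp,
      coverageMean = coverageMean, coverageSize = coverageSize,
      gcEffect = gcEffect, exonEffect = exonEffect,
      pvalueZeroMass = pvalueZeroMass,
      nReplicates = as.integer(nReplicates),
      batchScale = batchScale, detection = detection)
}

# VAF mixture: near-1 peak, near-0.5 peak, low-frequency tail.
.sampleTrueVaf <- function(n, weights) {
  comp <- sample.int(3L, n, replace = TRUE, prob = weights)
  vaf <- numeric(n)
  vaf[comp == 1L] <- stats::rbeta(sum(comp == 1L), 40, 1.5)
  vaf[comp == 2L] <- stats::rbeta(sum(comp == 2L), 60, 60)
  vaf[comp == 3L] <- 0.05 + 0.3 * stats::rbeta(sum(comp == 3L), 2, 3)
  list(vaf = vaf, component = comp)
}

# Annotation blocks tile the target in fixed proportions; exonic blocks get
# the capture-efficiency coverage boost.
.ANNOT_BLOCK_PROBS <- c(exonic = 0.30, intronic = 0.50, UTR3 = 0.07,
                        UTR5 = 0.05, upstream = 0.03, downstream = 0.03,
                        intergenic = 0.02)

#' Simulate a replicate set of SNV calls with ground truth
#'
#' Places \code{nTrueVariants} true variants once (shared across
#' replicates), then for each replicate draws per-position coverage from a
#' negative binomial whose mean combines the GC window, the annotation
#' block, a per-position capture efficiency shared across replicates (which
#' makes replicate coverages correlate below 1), a per-replicate total-read
#' factor, and the batch factor. True-variant VAC is Binomial(coverage,
#' VAF); the variant is emitted as a call only when it passes the detection
#' rule, so low coverage and low VAC cause dropout-driven discordance.
#' Independent false calls with VAC 1--5 are added per replicate. VAQ is
#' drawn higher for true calls (18--32) than false ones (5--20); confident
#' calls (VAC >= 10) get p-value 0 with probability \code{pvalueZeroMass},
#' all others Uniform(0, 1].
#'
#' All randomness is governed by \code{config@seed}: identical configs give
#' identical output.
#'
#' @param config a [SimulationConfig-class].
#' @param sampleIdStr sample identifier of the simulated set.
#' @param batchId batch identifier recorded on the replicates.
#' @param consensusMode \code{"full"} writes a consensus row for every
#'   target position (needed for whole-region concordance and GC/coverage
#'   summaries); \code{"variant"} restricts the consensus to positions
#'   involved in any call or true variant (compact; sufficient for SNV
#'   concordance, stratification, association and filtering).
#' @return list with \code{replicateSet} (a [ReplicateSet-class]),
#'   \code{truth} (data.frame: chrom, pos, is_true_variant, true_vaf,
#'   true_genotype, annotation, n_replicates_emitted), \code{gcTrack}
#'   (windowed GC table) and \code{config}.
#' @export
simulateReplicateSet <- function(config = simulationConfig(),
                                 sampleIdStr = "sim1",
                                 batchId = "batch1",
                                 consensusMode = c("full", "variant")) {
  stopifnot(is(config, "SimulationConfig"))
  methods::validObject(config)
  consensusMode <- match.arg(consensusMode)
  set.seed(config@seed, kind = "Mersenne-Twister")

  nbp <- config@nTargetBp
  chrom <- "chr1"
  windowSize <- 500L
  nWin <- ceiling(nbp / windowSize)

  # GC per window: loosely bimodal, modes astride 50%
  gcHigh <- stats::runif(nWin) < 0.4
  gc <- ifelse(gcHigh, stats::rbeta(nWin, 27, 18), stats::rbeta(nWin, 18, 27))
  gcTrack <- data.frame(chrom = chrom,
                        start = (seq_len(nWin) - 1L) * windowSize,
                        end = pmin(seq_len(nWin) * windowSize, nbp),
                        gc_fraction = gc, stringsAsFactors = FALSE)

  annotWin <- sample(names(.ANNOT_BLOCK_PROBS), nWin, replace = TRUE,
                     prob = .ANNOT_BLOCK_PROBS)
  refAll <- sample(.BASES, nbp, replace = TRUE)

  winOf <- function(pos) pmin((pos - 1L) %/% windowSize + 1L, nWin)
  muOf <- function(pos) {
    w <- winOf(pos)
    config@coverageMean * config@batchScale *
      ifelse(gc[w] >= 0.5, config@gcEffect, 1) *
      ifelse(annotWin[w] == "exonic", config@exonEffect, 1)
  }

  nTrue <- config@nTrueVariants
  truePos <- sort(sample.int(nbp, nTrue))
  mix <- .sampleTrueVaf(nTrue, config@vafMixture$weights)
  trueRef <- refAll[truePos]
  trueAlt <- vapply(trueRef, function(r)
    sample(setdiff(.BASES, r), 1L), character(1))
  homozygous <- mix$component == 1L  # near-1 VAF peak = homozygous variant
  trueGeno <- ifelse(homozygous,
                     genotypeString(trueAlt, trueAlt),
                     genotypeString(trueRef, trueAlt))

  # per-position capture efficiency shared across replicates
  eff <- stats::rgamma(nbp, shape = 3, rate = 3)
  det <- config@detection

  # latent per-variant allele quality, shared across replicates up to
  # per-replicate measurement noise: quality tracks the allele's sequence
  # context, so replicate VAQ values correlate
  vaqLatent <- 8 + 27 * stats::rbeta(nTrue, 2.2, 1.4)

  # false-call positions drawn up front so every replicate's consensus can
  # cover the union of call-relevant positions in compact mode
  nFalseEach <- stats::rpois(config@nReplicates,
                             config@errorRatePerBp * nbp)
  nonTrue <- setdiff(seq_len(nbp), truePos)
  falsePosList <- lapply(nFalseEach, function(k) sample(nonTrue, k))
  relevant <- sort(unique(c(truePos, unlist(falsePosList))))

  makeReplicate <- function(r) {
    repScale <- stats::rlnorm(1, 0, 0.15)
    muTrue <- muOf(truePos) * eff[truePos] * repScale
    covTrue <- stats::rnbinom(nTrue, size = config@coverageSize, mu = muTrue)
    vacTrue <- stats::rbinom(nTrue, covTrue, mix$vaf)
    detected <- if (isTRUE(det$enabled)) {
      pDet <- stats::pbinom(vacTrue - 1L, covTrue, det$errorP,
                            lower.tail = FALSE)
      vacTrue >= det$minVac & pDet <= det$alpha
    } else vacTrue >= 1L
    # broad, overlapping VAQ shapes: true calls tend higher but VAQ stays a
    # weakly informative factor, as observed for replicated capture data
    vaqTrue <- pmin(pmax(vaqLatent + stats::rnorm(nTrue, 0, 2), 0), 35)

    falsePos <- falsePosList[[r]]
    nFalse <- length(falsePos)
    covFalse <- stats::rnbinom(nFalse, size = config@coverageSize,
                               mu = muOf(falsePos) * eff[falsePos] * repScale)
    vacFalse <- sample(1:5, nFalse, replace = TRUE)
    covFalse <- pmax(covFalse, vacFalse)
    falseRef <- refAll[falsePos]
    falseAlt <- vapply(falseRef, function(x)
      sample(setdiff(.BASES, x), 1L), character(1))
    vaqFalse <- 3 + 27 * stats::rbeta(nFalse, 1.6, 1.9)

    vpos <- c(truePos[detected], falsePos)
    vdf <- data.frame(
      chrom = chrom, pos = vpos,
      ref = c(trueRef[detected], falseRef),
      genotype = c(trueGeno[detected],
                   genotypeString(falseRef, falseAlt)),
      variantAllele = c(trueAlt[detected], falseAlt),
      coverage = c(covTrue[detected], covFalse),
      vac = c(vacTrue[detected], vacFalse),
      vaq = c(vaqTrue[detected], vaqFalse),
      annotation = annotWin[winOf(vpos)],
      stringsAsFactors = FALSE)
    vdf$vaf <- ifelse(vdf$coverage > 0, vdf$vac / vdf$coverage, 0)
    conf <- vdf$vac >= 10
    pv <- stats::runif(nrow(vdf))
    pv[pv == 0] <- 1
    zero <- conf & stats::runif(nrow(vdf)) < config@pvalueZeroMass
    pv[zero] <- 0
    vdf$pvalue <- pv

    # consensus: every emitted call plus all true positions (sub-threshold
    # VAC is visible there), plus the rest of the target in full mode
    if (consensusMode == "full") {
      covAll <- stats::rnbinom(nbp, size = config@coverageSize,
                               mu = muOf(seq_len(nbp)) * eff * repScale)
      consPos <- seq_len(nbp)
    } else {
      consPos <- relevant
      covAll <- rep(NA_integer_, nbp)
      covAll[relevant] <- stats::rnbinom(
        length(relevant), size = config@coverageSize,
        mu = muOf(relevant) * eff[relevant] * repScale)
    }
    covAll[truePos] <- covTrue
    covAll[falsePos] <- covFalse
    cons <- data.frame(chrom = chrom, pos = consPos,
                       ref = refAll[consPos],
                       call = refAll[consPos],
                       coverage = covAll[consPos],
                       vac = 0L, vaf = 0, vaq = NA_real_,
                       pvalue = NA_real_, stringsAsFactors = FALSE)
    idxTrue <- match(truePos, consPos)
    cons$vac[idxTrue] <- vacTrue
    cons$vaf[idxTrue] <- ifelse(covTrue > 0, vacTrue / covTrue, 0)
    cons$vaq[idxTrue] <- vaqTrue
    mv <- match(vdf$pos, consPos)
    cons$call[mv] <- genotypeToCall(vdf$genotype)
    cons$vac[mv] <- vdf$vac
    cons$vaf[mv] <- vdf$vaf
    cons$vaq[mv] <- vdf$vaq
    cons$pvalue[mv] <- vdf$pvalue
    # ambiguous calls where the position has (almost) no reads
    ambig <- cons$coverage %in% 0L |
      (!is.na(cons$coverage) & cons$coverage < 3 &
         stats::runif(nrow(cons)) < 0.5)
    ambig[mv] <- FALSE
    cons$call[ambig] <- "N"
    list(cs = CallSet(sampleIdStr, sprintf("rep%d", r),
                      variants = vdf, consensus = cons),
         detected = detected)
  }

  reps <- lapply(seq_len(config@nReplicates), makeReplicate)
  nEmitted <- Reduce(`+`, lapply(reps, function(x)
    as.integer(x$detected)))
  truth <- data.frame(chrom = chrom, pos = truePos,
                      is_true_variant = TRUE,
                      true_vaf = mix$vaf, true_genotype = trueGeno,
                      annotation = annotWin[winOf(truePos)],
                      n_replicates_emitted = nEmitted,
                      stringsAsFactors = FALSE)
  list(replicateSet = ReplicateSet(lapply(reps, `[[`, "cs"),
                                   batchIds = rep(batchId,
                                                  config@nReplicates)),
       truth = truth, gcTrack = gcTrack, config = config)
}

#' Simulate several replicate sets across sequencing batches
#'
#' Each config gives one simulated sample; its \code{batchScale} scales the
#' total-read level of its batch, reproducing batch-to-batch variation in
#' the basic sequencing metrics.
#'
#' @param configs list of >= 2 [SimulationConfig-class] objects (give each
#'   its own seed).
#' @param batchIds batch label per config (default \code{"batch<i>"}).
#' @param sampleIds sample label per config (default \code{"sim<i>"}).
#' @param consensusMode passed to [simulateReplicateSet()].
#' @return list of results as returned by [simulateReplicateSet()].
#' @export
simulateBatches <- function(configs, batchIds = NULL, sampleIds = NULL,
                            consensusMode = "full") {
  if (length(configs) < 2L) stop("need at least 2 configs")
  if (is.null(batchIds))
    batchIds <- sprintf("batch%d", seq_along(configs))
  if (is.null(sampleIds))
    sampleIds <- sprintf("sim%d", seq_along(configs))
  Map(function(cfg, b, s)
    simulateReplicateSet(cfg, sampleIdStr = s, batchId = b,
                         consensusMode = consensusMode),
    configs, batchIds, sampleIds)
}
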