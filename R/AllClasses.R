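#' @import methods
NULL

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

.VARIANT_COLS <- c("chrom", "pos", "ref", "genotype", "variantAllele",
                   "coverage", "vac", "vaf", "vaq", "pvalue",
                   "annotation", "exonicClass", "maCategory")

.CONSENSUS_COLS <- c("chrom", "pos", "ref", "call", "coverage",
                     "vac", "vaf", "vaq", "pvalue")

.ANNOTATION_CLASSES <- c("exonic", "intronic", "UTR3", "UTR5", "intergenic",
                         "upstream", "downstream", "exonic_splicing",
                         "splicing", "ncRNA")

#' CallSet: variant and consensus calls from one sequencing replicate
#'
#' A \code{CallSet} holds the SNV calls of a single sequencing replicate as a
#' per-position table, optionally together with the per-position consensus
#' calls (genotype of every sequenced position, including ambiguous \code{N})
#' from which whole-region concordance is computed.
#'
#' The variant table has one row per called SNV with columns \code{chrom},
#' \code{pos} (1-based), \code{ref}, \code{genotype} (unordered allele pair
#' encoded as a sorted two-letter string, e.g. \code{"AG"}; homozygous =
#' \code{"GG"}), \code{variantAllele} (most abundant non-reference allele),
#' \code{coverage}, \code{vac} (variant allele count), \code{vaf} (variant
#' allele frequency), \code{vaq} (variant allele quality, 0--35),
#' \code{pvalue} (SNV-call p-value) and the optional annotation columns
#' \code{annotation}, \code{exonicClass}, \code{maCategory}.
#'
#' @slot sampleId character(1), the source-sample identifier.
#' @slot replicateId character(1), identifier of the replicate experiment.
#' @slot variants data.frame of SNV calls, unique per (chrom, pos).
#' @slot consensus optional data.frame of per-position consensus calls with
#'   columns \code{chrom, pos, ref, call, coverage, vac, vaf, vaq, pvalue};
#'   \code{call} is a base, an IUPAC heterozygous code, or \code{N}.
#' @slot metadata list of bookkeeping values (e.g. rows skipped on read).
#'
#' @seealso [readConsensusTable()], [readVcfCalls()], [snvConcordance()]
#' @export
setClass("CallSet",
         representation(sampleId = "character",
                        replicateId = "character",
                        variants = "data.frame",
                        consensus = "data.frameOrNULL",
                        metadata = "list"),
         prototype(sampleId = NA_character_, replicateId = NA_character_,
                   consensus = NULL, metadata = list()))

setValidity("CallSet", function(object) {
  msg <- character(0)
  v <- object@variants
  miss <- setdiff(.VARIANT_COLS, names(v))
  if (length(miss))
    msg <- c(msg, paste("variants table missing columns:",
                        paste(miss, collapse = ", ")))
  if (!length(msg) && nrow(v)) {
    key <- paste(v$chrom, v$pos)
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate (chrom, pos) keys in variants")
    bad <- !is.na(v$vac) & !is.na(v$coverage) & v$vac > v$coverage
    if (any(bad))
      msg <- c(msg, sprintf("%d variants with vac > coverage", sum(bad)))
    if (any(!is.na(v$vaf) & (v$vaf < 0 | v$vaf > 1)))
      msg <- c(msg, "vaf outside [0, 1]")
    same <- !is.na(v$variantAllele) & !is.na(v$ref) & v$variantAllele == v$ref
    if (any(same))
      msg <- c(msg, "variantAllele equal to ref")
    noVar <- !is.na(v$genotype) & !is.na(v$ref) &
      !vapply(seq_len(nrow(v)),
              function(i) grepl(sprintf("[^%s]", v$ref[i]), v$genotype[i]),
              logical(1))
    if (any(noVar))
      msg <- c(msg, "genotype contains no non-reference allele")
  }
  cn <- object@consensus
  if (!is.null(cn)) {
    missc <- setdiff(.CONSENSUS_COLS, names(cn))
    if (length(missc))
      msg <- c(msg, paste("consensus table missing columns:",
                          paste(missc, collapse = ", ")))
    else if (nrow(cn) && anyDuplicated(paste(cn$chrom, cn$pos)))
      msg <- c(msg, "duplicate (chrom, pos) keys in consensus")
  }
  if (length(msg)) msg else TRUE
})

#' ReplicateSet: 2 or 3 replicate call sets of the same sample
#'
#' @slot sampleId character(1) shared by all replicates.
#' @slot callSets list of 2 or 3 [CallSet-class] objects.
#' @slot batchIds character vector, one sequencing-batch id per replicate.
#'
#' @export
setClass("ReplicateSet",
         representation(sampleId = "character",
                        callSets = "list",
                        batchIds = "character"))

setValidity("ReplicateSet", function(object) {
  n <- length(object@callSets)
  if (n < 2L || n > 3L)
    return("a ReplicateSet needs 2 or 3 replicates")
  if (!all(vapply(object@callSets, is, logical(1), "CallSet")))
    return("callSets must all be CallSet objects")
  sids <- vapply(object@callSets, function(x) x@sampleId, character(1))
  if (length(unique(sids)) != 1L || !identical(sids[1], object@sampleId))
    return("all replicates must share the ReplicateSet sampleId")
  if (length(object@batchIds) != n)
    return("need one batchId per replicate")
  TRUE
})

#' ConcordanceResult: concordant count, per-replicate totals, rate
#'
#' Holds the concordance statistic \eqn{R_c = N_c / \mathrm{mean}(N_1, N_2)}
#' for one replicate pair, or its average across the three pairs of a
#' triplicate (in which case \code{pairResults} carries the per-pair results).
#'
#' @slot nConcordant numeric, concordant call count \eqn{N_c} (triplicates:
#'   mean across pairs).
#' @slot nTotal1,nTotal2 numeric, per-replicate call totals \eqn{N_1, N_2}.
#' @slot rate numeric in [0, 1].
#' @slot pairResults list of per-pair \code{ConcordanceResult}s (empty for a
#'   single pair).
#'
#' @export
setClass("ConcordanceResult",
         representation(nConcordant = "numeric",
                        nTotal1 = "numeric",
                        nTotal2 = "numeric",
                        rate = "numeric",
                        pairResults = "list"),
         prototype(pairResults = list()))

setValidity("ConcordanceResult", function(object) {
  if (object@rate < 0 || object@rate > 1)
    return("rate must lie in [0, 1]")
  if (!length(object@pairResults) &&
      object@nConcordant > min(object@nTotal1, object@nTotal2) + 1e-8)
    return("nConcordant exceeds min(nTotal1, nTotal2)")
  TRUE
})

#' BinScheme: ordered factor categories for stratified concordance
#'
#' Numeric schemes hold strictly increasing bin edges (left-closed,
#' right-open; final bin closed above) on an optionally log10-transformed
#' scale. Categorical schemes hold an ordered label set.
#'
#' @slot factorName character(1), e.g. \code{"coverage"} or \code{"vaf"}.
#' @slot type \code{"numeric"} or \code{"categorical"}.
#' @slot edges numeric edges (length nbins + 1) for numeric schemes.
#' @slot transform \code{"none"} or \code{"log10"}; values are transformed
#'   before edge lookup.
#' @slot labels character, one per bin (or the category set itself).
#' @slot metadata list (e.g. transition/transversion flags per substitution).
#'
#' @seealso [sturgesBins()], [empiricalCoverageBins()], [mergeTailBins()]
#' @export
setClass("BinScheme",
         representation(factorName = "character",
                        type = "character",
                        edges = "numeric",
                        transform = "character",
                        labels = "character",
                        metadata = "list"),
         prototype(type = "numeric", transform = "none", edges = numeric(0),
                   metadata = list()))

setValidity("BinScheme", function(object) {
  if (!object@type %in% c("numeric", "categorical"))
    return("type must be 'numeric' or 'categorical'")
  if (object@type == "numeric") {
    if (length(object@edges) < 2L)
      return("numeric scheme needs >= 2 edges")
    if (any(diff(object@edges) <= 0))
      return("edges must be strictly increasing")
    if (length(object@labels) != length(object@edges) - 1L)
      return("need one label per bin")
    if (!object@transform %in% c("none", "log10"))
      return("transform must be 'none' or 'log10'")
  } else if (!length(object@labels)) {
    return("categorical scheme needs labels")
  }
  TRUE
})

#' FilterCriteria: lower-bound thresholds on SNV-call factors
#'
#' A call survives when \code{coverage >= minCoverage & vac >= minVac &
#' vaf >= minVaf & vaq >= minVaq} and, when \code{maxPvalue} is set,
#' \code{pvalue <= maxPvalue}.
#'
#' @slot minCoverage,minVac numeric read-count thresholds (>= 0).
#' @slot minVaf numeric in [0, 1].
#' @slot minVaq numeric quality threshold (>= 0).
#' @slot maxPvalue numeric or NA (unset).
#'
#' @seealso [pooledCriteria()], [categorizedCriteria()], [applyFilter()]
#' @export
setClass("FilterCriteria",
         representation(minCoverage = "numeric", minVac = "numeric",
                        minVaf = "numeric", minVaq = "numeric",
                        maxPvalue = "numeric"),
         prototype(minCoverage = 0, minVac = 0, minVaf = 0, minVaq = 0,
                   maxPvalue = NA_real_))

setValidity("FilterCriteria", function(object) {
  if (object@minCoverage < 0 || object@minVac < 0 || object@minVaq < 0)
    return("thresholds must be >= 0")
  if (object@minVaf < 0 || object@minVaf > 1)
    return("minVaf must lie in [0, 1]")
  if (!is.na(object@maxPvalue) &&
      (object@maxPvalue < 0 || object@maxPvalue > 1))
    return("maxPvalue must lie in [0, 1]")
  TRUE
})

#' SimulationConfig: parameters of the synthetic replicate-call generator
#'
#' Defines the statistical structure of simulated replicate experiments:
#' shared true variants with a VAF mixture peaking near 1 with a lower peak
#' near 0.5, independent per-replicate false calls with low VAC/VAF,
#' negative-binomial coverage depressed in GC-rich windows, a point mass of
#' SNV-call p-values at 0, and detection-threshold dropout that ties
#' discordance causally to coverage and VAC.
#'
#' @slot seed integer seed used for all randomness of one simulated set.
#' @slot nTargetBp integer, size of the synthetic target region in bp.
#' @slot nTrueVariants integer, number of shared true variants.
#' @slot vafMixture list with numeric \code{weights} (sum 1) and component
#'   samplers for the near-1 peak, the near-0.5 peak and a low-VAF tail.
#' @slot errorRatePerBp expected false SNV calls per bp per replicate.
#' @slot coverageMean,coverageSize negative-binomial mean (low-GC windows)
#'   and size (dispersion) of per-position coverage.
#' @slot gcEffect multiplicative coverage factor for GC > 50\% windows.
#' @slot exonEffect multiplicative coverage factor for exonic blocks
#'   (capture baits target exons).
#' @slot pvalueZeroMass fraction of confident calls with p-value exactly 0.
#' @slot nReplicates 2 or 3.
#' @slot batchScale multiplicative total-read factor of the batch.
#' @slot detection list: \code{enabled}, \code{minVac}, \code{alpha},
#'   \code{errorP} — a true variant is emitted only if its sampled VAC passes
#'   \code{vac >= minVac} and a one-sided binomial test against the
#'   per-read error rate \code{errorP} at level \code{alpha}.
#'
#' @seealso [simulationConfig()], [simulateReplicateSet()]
#' @export
setClass("SimulationConfig",
         representation(seed = "integer",
                        nTargetBp = "integer",
                        nTrueVariants = "integer",
                        vafMixture = "list",
                        errorRatePerBp = "numeric",
                        coverageMean = "numeric",
                        coverageSize = "numeric",
                        gcEffect = "numeric",
                        exonEffect = "numeric",
                        pvalueZeroMass = "numeric",
                        nReplicates = "integer",
                        batchScale = "numeric",
                        detection = "list"))

setValidity("SimulationConfig", function(object) {
  if (object@nTargetBp < 1000L)
    return("nTargetBp must be >= 1000")
  if (object@nTrueVariants < 0L)
    return("nTrueVariants must be >= 0")
  w <- object@vafMixture$weights
  if (abs(sum(w) - 1) > 1e-8)
    return("vafMixture weights must sum to 1")
  if (object@errorRatePerBp < 0)
    return("errorRatePerBp must be >= 0")
  if (object@pvalueZeroMass < 0 || object@pvalueZeroMass > 1)
    return("pvalueZeroMass must lie in [0, 1]")
  if (!object@nReplicates %in% c(2L, 3L))
    return("nReplicates must be 2 or 3")
  if (object@nTrueVariants == 0L &&
      object@errorRatePerBp * object@nTargetBp < 1)
    return("degenerate config: expected call count is 0")
  TRUE
})
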