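#' @include association.R
NULL

.roundHalfUp <- function(x, digits = 0) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

#' Derive filter thresholds from the pooled reproduced calls
#'
#' Thresholds are the mean factor values of the reproduced (status = 1)
#' group of a pooled status table: coverage, VAC and VAQ rounded to
#' integers, VAF to one decimal.
#'
#' @param table a pooled status table from [poolStatus()].
#' @return a [FilterCriteria-class].
#' @seealso [pooledPreset()] for the fixed reference thresholds.
#' @export
pooledCriteria <- function(table) {
  rep1 <- table[table$status == 1, , drop = FALSE]
  if (!nrow(rep1)) stop("no reproduced (status = 1) calls")
  m <- function(col) mean(rep1[[col]], na.rm = TRUE)
  FilterCriteria(minCoverage = .roundHalfUp(m("coverage")),
                 minVac = .roundHalfUp(m("vac")),
                 minVaf = .roundHalfUp(m("vaf"), 1),
                 minVaq = .roundHalfUp(m("vaq")))
}

#' Reference threshold presets for reproducible SNV calls
#'
#' \code{pooledPreset()} is the pooled-reproduced-group preset established
#' for replicated kinome capture sequencing: min coverage 78, min VAC 45,
#' min VAF 0.6, min VAQ 22. \code{categorizedCriteria()} is the preset read
#' off the categorised (binned) concordance profiles: min coverage 20, min
#' VAC 20, min VAF 0.3, min VAQ 20 — field-wise weaker than the pooled
#' preset, so it always retains a superset of the calls.
#'
#' @return a [FilterCriteria-class].
#' @export
pooledPreset <- function() {
  FilterCriteria(minCoverage = 78, minVac = 45, minVaf = 0.6, minVaq = 22)
}

#' @rdname pooledPreset
#' @export
categorizedCriteria <- function() {
  FilterCriteria(minCoverage = 20, minVac = 20, minVaf = 0.3, minVaq = 20)
}

#' Filter a call set by factor thresholds
#'
#' Keeps variants with \code{coverage >= minCoverage}, \code{vac >= minVac},
#' \code{vaf >= minVaf}, \code{vaq >= minVaq}, and \code{pvalue <=
#' maxPvalue} when set. Per-rule removal counts land in the metadata
#' (a variant failing several rules is counted under each). Variants with a
#' missing value in an active (> 0) threshold field are dropped and counted
#' under \code{missing} by default; \code{keepMissing = TRUE} retains them.
#'
#' @param object a [CallSet-class].
#' @param criteria a [FilterCriteria-class].
#' @param keepMissing keep variants with NA in an active threshold field.
#' @return the filtered [CallSet-class]; metadata gains \code{filterRemoved}.
#' @export
setMethod("applyFilter", signature(object = "CallSet",
                                   criteria = "FilterCriteria"),
          function(object, criteria, keepMissing = FALSE) {
  v <- variantCalls(object)
  if (!nrow(v)) return(object)
  passGe <- function(x, thr) {
    if (thr <= 0) rep(TRUE, length(x))
    else ifelse(is.na(x), NA, x >= thr)
  }
  pass <- cbind(coverage = passGe(v$coverage, criteria@minCoverage),
                vac = passGe(v$vac, criteria@minVac),
                vaf = passGe(v$vaf, criteria@minVaf),
                vaq = passGe(v$vaq, criteria@minVaq),
                pvalue = if (is.na(criteria@maxPvalue))
                  rep(TRUE, nrow(v))
                else ifelse(is.na(v$pvalue), NA,
                            v$pvalue <= criteria@maxPvalue))
  removedPerRule <- colSums(!pass, na.rm = TRUE)
  hasMissing <- apply(is.na(pass), 1L, any)
  keep <- apply(pass, 1L, function(r) all(r %in% TRUE))
  if (keepMissing)
    keep <- keep | (hasMissing &
                    apply(pass, 1L, function(r) !any(r %in% FALSE)))
  md <- object@metadata
  md$filterRemoved <- c(as.list(removedPerRule),
                        list(missing = sum(hasMissing & !keep &
                                           apply(pass, 1L, function(r)
                                             !any(r %in% FALSE)))))
  CallSet(sampleId(object), replicateId(object),
          variants = v[keep, , drop = FALSE],
          consensus = consensusCalls(object), metadata = md)
})

#' Remove positions under a coverage floor in either replicate
#'
#' Drops every SNV position whose coverage (from the variant record, or the
#' consensus table where the position was not called) is below
#' \code{minCoverage} in either or both replicates, from both call sets.
#'
#' @param a,b [CallSet-class] replicates of one sample.
#' @param minCoverage coverage floor (default 20).
#' @return list with the filtered call sets \code{a} and \code{b}.
#' @export
coverageFilterPair <- function(a, b, minCoverage = 20) {
  va <- variantCalls(a)
  vb <- variantCalls(b)
  keys <- union(paste(va$chrom, va$pos), paste(vb$chrom, vb$pos))
  covA <- .factorValuesAt(a, keys, "coverage")
  covB <- .factorValuesAt(b, keys, "coverage")
  drop <- keys[is.na(covA) | is.na(covB) |
               covA < minCoverage | covB < minCoverage]
  subsetCs <- function(cs, v) {
    CallSet(sampleId(cs), replicateId(cs),
            variants = v[!(paste(v$chrom, v$pos) %in% drop), ,
                         drop = FALSE],
            consensus = consensusCalls(cs), metadata = cs@metadata)
  }
  list(a = subsetCs(a, va), b = subsetCs(b, vb))
}

#' Concordance before and after threshold filtering across pairs
#'
#' Applies \code{criteria} to every replicate of every set, recomputes the
#' (pairwise or triplicate-averaged) SNV concordance rate, and tests the
#' per-set change with a two-sided paired t-test. Sets emptied by the
#' filter are excluded with a warning and flagged in the output.
#'
#' @param repSets list of >= 2 [ReplicateSet-class] objects.
#' @param criteria a [FilterCriteria-class].
#' @return list: \code{perSet} data.frame (sample_id, rate_before,
#'   rate_after, excluded), \code{meanBefore}, \code{sdBefore},
#'   \code{meanAfter}, \code{sdAfter}, \code{pvalue} (NA with a
#'   \code{noDifference} flag when all changes are zero).
#' @export
filterEffect <- function(repSets, criteria) {
  if (length(repSets) < 2L) stop("need at least 2 replicate sets")
  before <- after <- rep(NA_real_, length(repSets))
  sampleIds <- vapply(repSets, sampleId, character(1))
  excluded <- logical(length(repSets))
  for (i in seq_along(repSets)) {
    rs <- repSets[[i]]
    before[i] <- concordanceRate(replicateConcordance(rs))
    filtered <- lapply(callSets(rs), applyFilter, criteria = criteria)
    if (all(vapply(filtered, function(cs) nrow(variantCalls(cs)) == 0,
                   TRUE))) {
      excluded[i] <- TRUE
      warning("set ", sampleId(rs), " emptied by filtering; excluded")
      next
    }
    after[i] <- concordanceRate(
      replicateConcordance(ReplicateSet(filtered, batchIds(rs))))
  }
  ok <- !excluded
  diffs <- after[ok] - before[ok]
  noDiff <- all(diffs == 0)
  p <- if (noDiff || sum(ok) < 2L) NA_real_ else
    stats::t.test(after[ok], before[ok], paired = TRUE,
                  alternative = "two.sided")$p.value
  list(perSet = data.frame(sample_id = sampleIds, rate_before = before,
                           rate_after = after, excluded = excluded,
                           stringsAsFactors = FALSE),
       meanBefore = mean(before[ok]), sdBefore = stats::sd(before[ok]),
       meanAfter = mean(after[ok]), sdAfter = stats::sd(after[ok]),
       pvalue = p, noDifference = noDiff)
}
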