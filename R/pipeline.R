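#' @include filtering.R
NULL

#' Build the standard bin schemes from pooled factor values
#'
#' Coverage uses the fixed empirical depth bins; VAC uses Sturges bins on
#' log10 values; VAF, VAQ and the SNV p-value use Sturges bins on the raw
#' scale. Sturges schemes are built from the pooled values of all SNV
#' positions across samples and then tail-merged against the pooled bin
#' counts, so the same scheme applies to every pair.
#'
#' @param table a pooled status table from [poolStatus()].
#' @param minCount tail-merge threshold passed to [mergeTailBins()].
#' @return named list of [BinScheme-class] objects
#'   (coverage, vac, vaf, vaq, pvalue).
#' @export
buildFactorSchemes <- function(table, minCount = NULL) {
  mk <- function(f, transform) {
    vals <- table[[f]]
    vals <- vals[!is.na(vals)]
    if (transform == "log10") vals <- vals[vals > 0]
    sc <- sturgesBins(vals, transform = transform, factorName = f)
    counts <- table(binAssign(sc, vals))
    mc <- if (is.null(minCount)) max(30, 0.001 * length(vals)) else minCount
    mergeTailBins(sc, as.numeric(counts), minCount = mc)
  }
  list(coverage = empiricalCoverageBins(),
       vac = mk("vac", "log10"),
       vaf = mk("vaf", "none"),
       vaq = mk("vaq", "none"),
       pvalue = mk("pvalue", "none"))
}

#' Serialise a BinScheme to JSON
#'
#' @param scheme a [BinScheme-class].
#' @param path optional output path; omitted, the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
binSchemeToJson <- function(scheme, path = NULL) {
  obj <- list(factor = scheme@factorName, type = scheme@type,
              transform = scheme@transform, edges = scheme@edges,
              labels = scheme@labels)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Run the full concordance pipeline and write a report bundle
#'
#' Executes, over a list of replicate sets: pooling of SNV calls into a
#' concordance-status table; per-sample concordance (SNV and, where full
#' consensus tables are present, whole-region rates); stratified
#' concordance per factor; factor association (mutual information, AIC,
#' lasso entry order, per-factor ANOVA R2); and threshold-filter evaluation
#' with the categorised preset and the data-derived pooled criteria. Five
#' report files are written under \code{outDir}: \code{concordance.tsv},
#' \code{stratified.tsv}, \code{association.json}, \code{filtering.tsv}
#' and \code{run_info.json}; every file name is returned. The run seed and
#' a fingerprint of the inputs go into \code{run_info.json}.
#'
#' Inputs are never mutated; a stage failure aborts with the stage name,
#' leaving the reports of completed stages in place.
#'
#' @param repSets list of [ReplicateSet-class] objects (>= 2 for the
#'   filtering stage's paired test).
#' @param outDir output directory (created if missing).
#' @param seed integer recorded in the outputs and set before the
#'   association stage (the lasso path itself is deterministic; the seed
#'   guards any downstream resampling).
#' @return named list of written file paths, invisibly.
#' @export
runPipeline <- function(repSets, outDir, seed = 1L) {
  if (is(repSets, "ReplicateSet")) repSets <- list(repSets)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  set.seed(as.integer(seed))

  pooled <- stage("pool", poolStatus(repSets))

  concRows <- stage("concord", {
    do.call(rbind, lapply(repSets, function(rs) {
      res <- replicateConcordance(rs)
      allc <- tryCatch(
        concordanceRate(replicateConcordance(rs, statistic = "allcall")),
        error = function(e) NA_real_)
      data.frame(sample_id = sampleId(rs),
                 replicate_type = if (length(callSets(rs)) == 3) "Trp"
                                  else "Dup",
                 n_concordant = res@nConcordant,
                 n1 = res@nTotal1, n2 = res@nTotal2,
                 snv_rate = concordanceRate(res),
                 snv_pct = percentRate(concordanceRate(res), 1),
                 allcall_rate = allc,
                 stringsAsFactors = FALSE)
    }))
  })
  files$concordance <- file.path(outDir, "concordance.tsv")
  utils::write.table(concRows, files$concordance, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  schemes <- stage("stratify-schemes", buildFactorSchemes(pooled))
  strat <- stage("stratify", {
    do.call(rbind, lapply(names(schemes), function(f) {
      s <- stratifyReplicateSets(repSets, schemes[[f]])
      cbind(factor = f, s@summary, stringsAsFactors = FALSE)
    }))
  })
  files$stratified <- file.path(outDir, "stratified.tsv")
  utils::write.table(strat, files$stratified, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  assoc <- stage("associate", {
    summ <- associationSummary(pooled, schemes)
    r2 <- lapply(names(schemes), function(f) {
      s <- stratifyReplicateSets(repSets, schemes[[f]])
      tryCatch(factorR2(s), error = function(e)
        list(r2 = NA_real_, pvalue = NA_real_))
    })
    summ$r2 <- vapply(r2, function(x) x$r2, 1)
    summ$anova_pvalue <- vapply(r2, function(x) x$pvalue, 1)
    summ
  })
  files$association <- file.path(outDir, "association.json")
  jsonlite::write_json(assoc, files$association, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null")

  filt <- stage("filter", {
    eff <- filterEffect(repSets, categorizedCriteria())
    pc <- pooledCriteria(pooled)
    effPooled <- filterEffect(repSets, pc)
    data.frame(
      condition = c("unfiltered", "pooled_criteria",
                    "categorized_criteria"),
      mean_rate = c(eff$meanBefore, effPooled$meanAfter, eff$meanAfter),
      sd_rate = c(eff$sdBefore, effPooled$sdAfter, eff$sdAfter),
      pvalue_vs_unfiltered = c(NA, effPooled$pvalue, eff$pvalue),
      min_coverage = c(0, pc@minCoverage, 20),
      min_vac = c(0, pc@minVac, 20),
      min_vaf = c(0, pc@minVaf, 0.3),
      min_vaq = c(0, pc@minVaq, 20),
      stringsAsFactors = FALSE)
  })
  files$filtering <- file.path(outDir, "filtering.tsv")
  utils::write.table(filt, files$filtering, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  info <- list(
    tool = "ReplicateConcordance",
    version = as.character(utils::packageVersion("ReplicateConcordance")),
    seed = as.integer(seed),
    n_replicate_sets = length(repSets),
    input_fingerprint = .configHash(lapply(repSets, function(rs)
      lapply(callSets(rs), variantCalls))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  files$runInfo <- file.path(outDir, "run_info.json")
  jsonlite::write_json(info, files$runInfo, auto_unbox = TRUE)

  invisible(files)
}
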