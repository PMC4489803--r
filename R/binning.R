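#' @include methods-accessors.R
NULL

#' StratifiedConcordance: per-bin concordance of one factor
#'
#' @slot factorName the stratifying factor.
#' @slot perPair data.frame with one row per (pair, bin): sample_id, pair,
#'   bin, n_positions, n_concordant, n1, n2, rate.
#' @slot summary data.frame with one row per bin: bin, n_positions
#'   (total), mean_rate across pairs.
#'
#' @seealso [concordanceByFactor()], [stratifyReplicateSets()]
#' @export
setClass("StratifiedConcordance",
         representation(factorName = "character",
                        perPair = "data.frame",
                        summary = "data.frame"))

setMethod("show", "StratifiedConcordance", function(object) {
  cat("StratifiedConcordance:", object@factorName, "\n")
  print(object@summary, row.names = FALSE)
})

.binLabelsFromEdges <- function(edges) {
  n <- length(edges) - 1L
  lab <- character(n)
  for (i in seq_len(n)) {
    lab[i] <- if (i < n)
      sprintf("[%.4g,%.4g)", edges[i], edges[i + 1])
    else sprintf("[%.4g,%.4g]", edges[i], edges[i + 1])
  }
  lab
}

#' The empirical coverage-depth bin scheme
#'
#' Five fixed depth categories: 1-4x, 5-19x, 20-79x, 80-199x, >=200x.
#' Positions with zero coverage fall outside the scheme.
#'
#' @return a [BinScheme-class] for factor \code{"coverage"}.
#' @export
empiricalCoverageBins <- function() {
  new("BinScheme", factorName = "coverage", type = "numeric",
      edges = c(1, 5, 20, 80, 200, Inf), transform = "none",
      labels = c("1-4x", "5-19x", "20-79x", "80-199x", ">=200x"))
}

#' Equal-width bins by Sturges' rule
#'
#' The bin count is \eqn{k = \lceil \log_2 n + 1 \rceil} for \eqn{n} pooled
#' values; bins are equal-width over the observed range of the (optionally
#' log10-transformed) values. Left-closed, right-open; the final bin is
#' closed above so the maximum is covered.
#'
#' @param values pooled numeric factor values over all samples.
#' @param transform \code{"none"} or \code{"log10"} (requires positive
#'   values; used for variant allele count).
#' @param factorName label carried by the scheme.
#' @return a [BinScheme-class].
#' @export
sturgesBins <- function(values, transform = c("none", "log10"),
                        factorName = "factor") {
  transform <- match.arg(transform)
  x <- as.numeric(values)
  x <- x[!is.na(x)]
  if (!length(x)) stop("no non-missing values to bin")
  if (transform == "log10") {
    if (any(x <= 0)) stop("log10 transform requires positive values")
    x <- log10(x)
  }
  rng <- range(x)
  if (diff(rng) == 0) {
    warning("constant values: single-bin scheme")
    edges <- c(rng[1] - 0.5, rng[1] + 0.5)
  } else {
    k <- ceiling(log2(length(x)) + 1)
    edges <- seq(rng[1], rng[2], length.out = k + 1L)
  }
  new("BinScheme", factorName = factorName, type = "numeric",
      edges = edges, transform = transform,
      labels = .binLabelsFromEdges(edges))
}

#' Merge sparsely populated tail bins
#'
#' Tail bins holding fewer than \code{minCount} positions are combined: a
#' run of two or more sparse bins at a tail is combined together into one
#' bin (kept even if the combined count is still small), while a lone
#' sparse tail bin, having no sparse neighbour to combine with, is absorbed
#' into the adjacent interior bin. Interior bins are never touched, so the
#' result is a coarsening of the input scheme: no value changes relative
#' order.
#'
#' @param scheme a numeric [BinScheme-class].
#' @param counts per-bin position counts aligned to the scheme.
#' @param minCount merge threshold; default \code{max(30, 0.1\%)} of the
#'   total count.
#' @return a [BinScheme-class] with merged tails.
#' @export
mergeTailBins <- function(scheme, counts,
                          minCount = max(30, 0.001 * sum(counts))) {
  stopifnot(is(scheme, "BinScheme"))
  if (scheme@type != "numeric")
    stop("tail merging applies to numeric schemes only")
  if (length(counts) != length(scheme@labels))
    stop("counts must align with the scheme's bins")
  cnt <- as.numeric(counts)
  nb <- length(cnt)
  sparse <- cnt < minCount
  if (all(sparse)) {
    warning("all bins below minCount: single-bin scheme")
    edges <- scheme@edges[c(1L, nb + 1L)]
  } else {
    left <- if (sparse[1]) {
      r <- rle(sparse)$lengths[1]
      if (r >= 2L) r else 2L  # lone sparse bin absorbs into its neighbour
    } else 1L
    rightRun <- if (sparse[nb]) utils::tail(rle(sparse)$lengths, 1) else 0L
    right <- if (rightRun >= 2L) rightRun else if (rightRun == 1L) 2L else 1L
    # keep edge 1, the edges between interior bins, and the last edge;
    # drop the edges interior to each merged tail run
    keepEdge <- rep(TRUE, nb + 1L)
    if (left > 1L) keepEdge[2:left] <- FALSE
    if (right > 1L) keepEdge[(nb + 2L - right):(nb)] <- FALSE
    edges <- scheme@edges[keepEdge]
  }
  new("BinScheme", factorName = scheme@factorName, type = "numeric",
      edges = edges, transform = scheme@transform,
      labels = .binLabelsFromEdges(edges), metadata = scheme@metadata)
}

#' Categorical bin schemes: substitution type and genome annotation
#'
#' \code{"substitution"} gives the 12 ordered ref>alt substitution
#' categories, with the transition flag (A>G, G>A, C>T, T>C) in the scheme
#' metadata; the other eight are transversions. \code{"annotation"} gives
#' the ten genome-annotation classes.
#'
#' @param factorName \code{"substitution"} or \code{"annotation"}.
#' @return a categorical [BinScheme-class].
#' @export
categoricalScheme <- function(factorName = c("substitution", "annotation")) {
  factorName <- match.arg(factorName)
  if (factorName == "substitution") {
    labs <- as.vector(outer(.BASES, .BASES, function(a, b)
      paste0(a, ">", b)))
    labs <- sort(labs[substr(labs, 1, 1) != substr(labs, 3, 3)])
    transitions <- c("A>G", "G>A", "C>T", "T>C")
    new("BinScheme", factorName = "substitution", type = "categorical",
        labels = labs,
        metadata = list(transition = stats::setNames(
          labs %in% transitions, labs)))
  } else {
    new("BinScheme", factorName = "annotation", type = "categorical",
        labels = .ANNOTATION_CLASSES)
  }
}

#' Two-class GC-content scheme split at 50%
#'
#' GC content is bimodal with the modes separated at 50%; concordance is
#' stratified into GC-low ([0, 0.5)) and GC-high ([0.5, 1]) windows.
#'
#' @return a [BinScheme-class] for factor \code{"gc"}.
#' @export
gcScheme <- function() {
  new("BinScheme", factorName = "gc", type = "numeric",
      edges = c(0, 0.5, 1), transform = "none",
      labels = c("GC<50%", "GC>=50%"))
}

# Factor values of one replicate at a set of (chrom,pos) keys. Numeric
# factors come from the replicate's own variant record, falling back on its
# consensus row where the position was not called; positional attributes
# (substitution, annotation, gc) are taken from whichever replicate called
# the variant.
.factorValuesAt <- function(callSet, keys, factorName, gcTrack = NULL) {
  v <- variantCalls(callSet)
  kv <- paste(v$chrom, v$pos)
  m <- match(keys, kv)
  if (factorName %in% c("coverage", "vac", "vaf", "vaq", "pvalue")) {
    out <- as.numeric(v[[factorName]][m])
    cn <- consensusCalls(callSet)
    if (!is.null(cn) && any(is.na(m))) {
      kc <- paste(cn$chrom, cn$pos)
      mc <- match(keys[is.na(m)], kc)
      out[is.na(m)] <- as.numeric(cn[[factorName]][mc])
    }
    out
  } else if (factorName == "substitution") {
    ifelse(is.na(m), NA_character_,
           paste0(v$ref[m], ">", v$variantAllele[m]))
  } else if (factorName == "annotation") {
    v$annotation[m]
  } else if (factorName == "gc") {
    if (is.null(gcTrack)) stop("gc stratification needs a gcTrack")
    chrom <- sub(" [0-9]+$", "", keys)
    pos <- as.integer(sub("^.* ", "", keys))
    gcAt(gcTrack, chrom, pos)
  } else {
    stop("unknown factor: ", factorName)
  }
}

#' Concordance stratified by a factor under the same-bin pairing rule
#'
#' For one replicate pair, every SNV position (called in either replicate)
#' is assigned to a bin of \code{scheme} once per replicate, using that
#' replicate's own factor value (the consensus-table value supplies it where
#' the position was not called there). Only positions falling in the same
#' bin in both replicates are kept; positions in different bins are
#' disregarded for this factor. Within each bin the genotype concordance
#' rule applies: \eqn{N_c} = both called with identical genotype,
#' \eqn{N_1}/\eqn{N_2} = per-replicate call counts in the bin, rate
#' \eqn{= N_c/\mathrm{mean}(N_1,N_2)}.
#'
#' For positional attributes (substitution type, annotation, GC content)
#' the value of the replicate that called the variant is used for both
#' sides, so the same-bin rule never discards them.
#'
#' @param a,b [CallSet-class] replicates of one sample.
#' @param scheme a [BinScheme-class]; its \code{factorName} selects the
#'   factor (\code{coverage}, \code{vac}, \code{vaf}, \code{vaq},
#'   \code{pvalue}, \code{substitution}, \code{annotation}, \code{gc}).
#' @param gcTrack windowed GC table (from [readGcTrack()]), required for
#'   the gc factor.
#' @return data.frame with one row per bin: bin, n_positions,
#'   n_concordant, n1, n2, rate (NA where the bin holds no calls).
#' @export
concordanceByFactor <- function(a, b, scheme, gcTrack = NULL) {
  stopifnot(is(scheme, "BinScheme"))
  factorName <- scheme@factorName
  va <- variantCalls(a)
  vb <- variantCalls(b)
  ka <- paste(va$chrom, va$pos)
  kb <- paste(vb$chrom, vb$pos)
  keys <- union(ka, kb)
  fa <- .factorValuesAt(a, keys, factorName, gcTrack)
  fb <- .factorValuesAt(b, keys, factorName, gcTrack)
  positional <- factorName %in% c("substitution", "annotation", "gc")
  if (positional) {
    fa <- ifelse(is.na(fa), fb, fa)
    fb <- fa
  }
  binA <- binAssign(scheme, fa)
  binB <- binAssign(scheme, fb)
  keep <- !is.na(binA) & !is.na(binB) & binA == binB
  gA <- va$genotype[match(keys, ka)]
  gB <- vb$genotype[match(keys, kb)]
  res <- data.frame(bin = binLabels(scheme), n_positions = 0L,
                    n_concordant = 0L, n1 = 0L, n2 = 0L, rate = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(res$bin)) {
    sel <- keep & binA == res$bin[i]
    n1 <- sum(sel & !is.na(gA))
    n2 <- sum(sel & !is.na(gB))
    nc <- sum(sel & !is.na(gA) & !is.na(gB) & gA == gB)
    res$n_positions[i] <- sum(sel)
    res$n_concordant[i] <- nc
    res$n1[i] <- n1
    res$n2[i] <- n2
    res$rate[i] <- if (n1 + n2 > 0) nc / mean(c(n1, n2)) else NA_real_
  }
  res
}

#' Stratified concordance across all replicate pairs
#'
#' Applies [concordanceByFactor()] to every pair of every
#' [ReplicateSet-class] and assembles the per-pair-per-bin rates that feed
#' the per-factor ANOVA ([factorR2()]).
#'
#' @param repSets list of [ReplicateSet-class] objects.
#' @param scheme a [BinScheme-class].
#' @param gcTrack optional GC track for the gc factor.
#' @return a [StratifiedConcordance-class].
#' @export
stratifyReplicateSets <- function(repSets, scheme, gcTrack = NULL) {
  rows <- list()
  for (rs in repSets) {
    cs <- callSets(rs)
    idx <- utils::combn(length(cs), 2L)
    for (j in seq_len(ncol(idx))) {
      i1 <- idx[1, j]; i2 <- idx[2, j]
      tab <- concordanceByFactor(cs[[i1]], cs[[i2]], scheme, gcTrack)
      tab$sample_id <- sampleId(rs)
      tab$pair <- sprintf("%s:%d-%d", sampleId(rs), i1, i2)
      rows[[length(rows) + 1L]] <- tab
    }
  }
  perPair <- do.call(rbind, rows)
  summary <- data.frame(
    bin = binLabels(scheme),
    n_positions = vapply(binLabels(scheme), function(b)
      sum(perPair$n_positions[perPair$bin == b], na.rm = TRUE), 1),
    mean_rate = vapply(binLabels(scheme), function(b) {
      r <- perPair$rate[perPair$bin == b]
      if (all(is.na(r))) NA_real_ else mean(r, na.rm = TRUE)
    }, 1),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  new("StratifiedConcordance", factorName = scheme@factorName,
      perPair = perPair, summary = summary)
}
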