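#' @include concordance.R
NULL

#' Published concordance counts for 17 replicated kinome capture samples
#'
#' Loads the per-pair concordant/total call counts reported for a replicated
#' targeted kinome (~3.2 Mb) sequencing study of 17 breast cancer samples —
#' 14 sequenced in duplicate, 3 in triplicate (one row per replicate pair;
#' triplicates contribute three rows). Counts cover both all-unambiguous
#' nucleotide calls over the sequenced region and SNV calls; the totals are
#' the pair means \eqn{\mathrm{mean}(N_1, N_2)}, as conventionally printed.
#'
#' @return data.frame with columns sample_id, replicate_type (Dup/Trp),
#'   pair_index, allcall_concordant, allcall_total, snv_concordant,
#'   snv_total.
#' @seealso [summarizeCountTable()]
#' @export
kinomeReplicateCounts <- function() {
  path <- system.file("extdata", "kinome_replicate_counts.tsv",
                      package = "ReplicateConcordance", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "character", "integer",
                                   "numeric", "numeric", "numeric",
                                   "numeric"),
                    stringsAsFactors = FALSE)
}

#' Concordance rate from printed concordant/total counts
#'
#' Applies the rate formula \eqn{R_c = N_c / N_{total}} where
#' \eqn{N_{total}} is the printed pair mean of the two replicates' totals.
#'
#' @param nConcordant concordant call count \eqn{N_c}.
#' @param nTotal pair-mean total \eqn{\mathrm{mean}(N_1, N_2)}.
#' @return a [ConcordanceResult-class].
#' @export
concordanceFromCounts <- function(nConcordant, nTotal) {
  .concordanceResult(nConcordant, nTotal, nTotal)
}

#' Per-sample concordance summary of a pair-level count table
#'
#' Computes the pairwise rates with [concordanceFromCounts()] and summarises
#' each sample by its single pairwise rate (duplicates) or the unweighted
#' mean of its three pairwise rates (triplicates), for both the
#' all-unambiguous-call and the SNV statistics. Percentages are rounded
#' half-up to the conventional precision (4 decimals all-call, 1 SNV).
#'
#' @param counts a count table in the layout of [kinomeReplicateCounts()].
#' @return list with \code{perPair} (pair-level rates) and \code{perSample}
#'   (sample-level summary with snv_pct and allcall_pct).
#' @export
summarizeCountTable <- function(counts) {
  counts$snv_rate <- counts$snv_concordant / counts$snv_total
  counts$allcall_rate <- counts$allcall_concordant / counts$allcall_total
  ids <- unique(counts$sample_id)
  perSample <- do.call(rbind, lapply(ids, function(id) {
    sub <- counts[counts$sample_id == id, , drop = FALSE]
    data.frame(sample_id = id,
               replicate_type = sub$replicate_type[1],
               n_pairs = nrow(sub),
               snv_rate = mean(sub$snv_rate),
               allcall_rate = mean(sub$allcall_rate),
               snv_pct = percentRate(mean(sub$snv_rate), 1),
               allcall_pct = percentRate(mean(sub$allcall_rate), 4),
               stringsAsFactors = FALSE)
  }))
  rownames(perSample) <- NULL
  list(perPair = counts, perSample = perSample)
}
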