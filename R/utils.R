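#' @include AllClasses.R
NULL

.BASES <- c("A", "C", "G", "T")

# IUPAC ambiguity codes for the six heterozygous base pairs
.IUPAC_HET <- c(R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")

#' Encode an unordered allele pair as a canonical genotype string
#'
#' Genotypes are stored as sorted two-letter strings so that unordered-pair
#' equality is plain string equality: \code{genotypeString("G","A") == "AG"}.
#'
#' @param a,b single bases in A/C/G/T.
#' @return character genotype string(s).
#' @export
genotypeString <- function(a, b) {
  stopifnot(all(a %in% .BASES), all(b %in% .BASES))
  ifelse(a <= b, paste0(a, b), paste0(b, a))
}

#' Decode a consensus call symbol into a genotype string
#'
#' A plain base decodes to the homozygous pair; an IUPAC two-base code
#' (R, Y, S, W, K, M) decodes to the heterozygous pair; \code{N} (ambiguous)
#' and anything else decode to NA — an ambiguous call is never a genotype.
#'
#' @param call character vector of consensus call symbols.
#' @return character vector of genotype strings, NA where ambiguous.
#' @export
callToGenotype <- function(call) {
  out <- rep(NA_character_, length(call))
  hom <- call %in% .BASES
  out[hom] <- paste0(call[hom], call[hom])
  het <- call %in% names(.IUPAC_HET)
  out[het] <- unname(.IUPAC_HET[call[het]])
  out
}

#' Encode a genotype string as a consensus call symbol
#'
#' Inverse of [callToGenotype()]: homozygous pairs give the base itself,
#' heterozygous pairs the IUPAC code.
#'
#' @param genotype character vector of sorted two-letter genotype strings.
#' @return character vector of call symbols.
#' @export
genotypeToCall <- function(genotype) {
  out <- rep(NA_character_, length(genotype))
  a <- substr(genotype, 1, 1)
  b <- substr(genotype, 2, 2)
  hom <- !is.na(genotype) & a == b
  out[hom] <- a[hom]
  map <- stats::setNames(names(.IUPAC_HET), .IUPAC_HET)
  het <- !is.na(genotype) & a != b
  out[het] <- unname(map[genotype[het]])
  out
}

# Most abundant non-reference allele of a genotype; with both alleles
# non-reference the first (alphabetical) is taken, the per-allele depths
# needed to break the tie not being part of the consensus dialect.
.variantAlleleOf <- function(genotype, ref) {
  a <- substr(genotype, 1, 1)
  b <- substr(genotype, 2, 2)
  out <- ifelse(a != ref, a, ifelse(b != ref, b, NA_character_))
  out[is.na(genotype) | is.na(ref)] <- NA_character_
  out
}

# Fill missing optional columns, order columns canonically.
.normalizeVariants <- function(df) {
  if (is.null(df)) df <- data.frame()
  for (col in .VARIANT_COLS) {
    if (!col %in% names(df)) {
      df[[col]] <- if (col %in% c("pos", "coverage", "vac"))
        rep(NA_integer_, nrow(df))
      else if (col %in% c("vaf", "vaq", "pvalue"))
        rep(NA_real_, nrow(df))
      else rep(NA_character_, nrow(df))
    }
  }
  df <- df[.VARIANT_COLS]
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  if (nrow(df)) df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  df
}

.normalizeConsensus <- function(df) {
  if (is.null(df)) return(NULL)
  for (col in .CONSENSUS_COLS) {
    if (!col %in% names(df)) {
      df[[col]] <- if (col %in% c("pos", "coverage", "vac"))
        rep(NA_integer_, nrow(df))
      else if (col %in% c("vaf", "vaq", "pvalue"))
        rep(NA_real_, nrow(df))
      else rep(NA_character_, nrow(df))
    }
  }
  df <- df[.CONSENSUS_COLS]
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  if (nrow(df)) df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Construct a CallSet
#'
#' @param sampleId,replicateId identifiers.
#' @param variants data.frame of SNV calls; missing optional columns are
#'   added as NA. Must be unique per (chrom, pos).
#' @param consensus optional data.frame of per-position consensus calls.
#' @param metadata list of bookkeeping values.
#' @return a validated [CallSet-class].
#' @examples
#' cs <- CallSet("s1", "r1", data.frame(
#'   chrom = "chr1", pos = 100L, ref = "A", genotype = "AG",
#'   variantAllele = "G", coverage = 50L, vac = 20L, vaf = 0.4,
#'   vaq = 28, pvalue = 0))
#' variantCalls(cs)
#' @export
CallSet <- function(sampleId, replicateId, variants = data.frame(),
                    consensus = NULL, metadata = list()) {
  new("CallSet", sampleId = as.character(sampleId),
      replicateId = as.character(replicateId),
      variants = .normalizeVariants(variants),
      consensus = .normalizeConsensus(consensus),
      metadata = metadata)
}

#' Construct a ReplicateSet
#'
#' @param callSets list of 2 or 3 [CallSet-class] objects sharing a sampleId.
#' @param batchIds sequencing-batch id per replicate (defaults to "batch1").
#' @return a validated [ReplicateSet-class].
#' @export
ReplicateSet <- function(callSets, batchIds = NULL) {
  if (is.null(batchIds)) batchIds <- rep("batch1", length(callSets))
  new("ReplicateSet",
      sampleId = if (length(callSets)) callSets[[1]]@sampleId else NA_character_,
      callSets = callSets, batchIds = as.character(batchIds))
}

#' Construct a FilterCriteria
#'
#' @param minCoverage,minVac,minVaf,minVaq lower bounds (default 0).
#' @param maxPvalue optional upper bound on the SNV-call p-value.
#' @return a validated [FilterCriteria-class].
#' @export
FilterCriteria <- function(minCoverage = 0, minVac = 0, minVaf = 0,
                           minVaq = 0, maxPvalue = NA_real_) {
  new("FilterCriteria", minCoverage = minCoverage, minVac = minVac,
      minVaf = minVaf, minVaq = minVaq, maxPvalue = as.numeric(maxPvalue))
}

# Polynomial rolling hash over the serialized object; stable fingerprint for
# run provenance (mod 2^31 - 1 keeps the arithmetic exact in doubles).
.configHash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 257 + b + 1) %% 2147483647
  sprintf("%08x", as.integer(h))
}
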