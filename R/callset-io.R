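#' @include utils.R
NULL

#' Read a per-position consensus-call table
#'
#' Reads the tab-separated consensus dialect: a header line
#' \code{#chrom pos ref call coverage vac vaf vaq pvalue} followed by one row
#' per sequenced position, \code{.} for missing values. \code{call} is a
#' plain base (homozygous), an IUPAC two-base code (heterozygous) or \code{N}
#' (ambiguous). Rows whose call differs from the reference base (and is not
#' \code{N}) additionally yield SNV entries in the variant table, with the
#' row's factor values attached. Optional trailing columns
#' \code{annotation}, \code{exonic_class} and \code{ma_category} are carried
#' onto those variant entries.
#'
#' Rows with non-numeric coverage or with \code{vac > coverage} are rejected
#' with a warning naming the offending line numbers; the counts are recorded
#' in the CallSet metadata so that parsed + skipped always equals the input
#' row count.
#'
#' @param path path to the TSV file.
#' @param sampleId,replicateId identifiers for the resulting CallSet.
#' @return a [CallSet-class] with both consensus and variant tables.
#' @seealso [writeConsensusTable()]
#' @export
readConsensusTable <- function(path, sampleId = "sample",
                               replicateId = basename(path)) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#"))
    stop("consensus table ", path, ": missing '#'-prefixed header line")
  header <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
  required <- c("chrom", "pos", "ref", "call", "coverage",
                "vac", "vaf", "vaq", "pvalue")
  miss <- setdiff(required, header)
  if (length(miss))
    stop("consensus table ", path, ": missing required column(s) ",
         paste(miss, collapse = ", "))
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (!length(body))
    return(CallSet(sampleId, replicateId,
                   consensus = data.frame(),
                   metadata = list(inputRows = 0L, skippedRows = 0L)))
  df <- utils::read.table(text = body, sep = "\t", col.names = header,
                          na.strings = ".", colClasses = "character",
                          quote = "", comment.char = "")
  lineNo <- seq_len(nrow(df)) + 1L

  numify <- function(x) suppressWarnings(as.numeric(x))
  cov <- numify(df$coverage)
  badCov <- !is.na(df$coverage) & is.na(cov)
  pos <- numify(df$pos)
  badPos <- is.na(pos)
  vac <- numify(df$vac)
  badVac <- !is.na(df$vac) & is.na(vac)
  badInv <- !is.na(vac) & !is.na(cov) & vac > cov
  bad <- badCov | badPos | badVac | badInv
  if (any(bad)) {
    warning(sprintf(
      "consensus table %s: rejected %d row(s) (lines %s): %s",
      path, sum(bad), paste(lineNo[bad], collapse = ","),
      paste(unique(c(
        if (any(badCov | badPos | badVac)) "non-numeric field",
        if (any(badInv)) "vac > coverage")), collapse = "; ")))
  }
  keep <- !bad
  cons <- data.frame(chrom = df$chrom[keep], pos = as.integer(pos[keep]),
                     ref = df$ref[keep], call = df$call[keep],
                     coverage = as.integer(cov[keep]),
                     vac = as.integer(vac[keep]),
                     vaf = numify(df$vaf)[keep], vaq = numify(df$vaq)[keep],
                     pvalue = numify(df$pvalue)[keep],
                     stringsAsFactors = FALSE)

  isVar <- !is.na(cons$call) & cons$call != "N" & !is.na(cons$ref) &
    cons$call != cons$ref
  vdf <- cons[isVar, , drop = FALSE]
  if (nrow(vdf)) {
    vdf$genotype <- callToGenotype(vdf$call)
    vdf$variantAllele <- .variantAlleleOf(vdf$genotype, vdf$ref)
    vdf$call <- NULL
    extras <- c(annotation = "annotation", exonicClass = "exonic_class",
                maCategory = "ma_category")
    for (tgt in names(extras)) {
      if (extras[[tgt]] %in% header)
        vdf[[tgt]] <- df[[extras[[tgt]]]][keep][isVar]
    }
  }
  CallSet(sampleId, replicateId, variants = vdf, consensus = cons,
          metadata = list(inputRows = nrow(df), skippedRows = sum(bad)))
}

#' Write a CallSet's consensus table in the consensus dialect
#'
#' Field-exact inverse of [readConsensusTable()]: missing values become
#' \code{.}, the header is \code{#}-prefixed and tab-separated.
#'
#' @param object a [CallSet-class] with a consensus table.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeConsensusTable <- function(object, path) {
  cn <- consensusCalls(object)
  if (is.null(cn)) stop("CallSet has no consensus table")
  fmt <- function(x) {
    out <- as.character(x)
    out[is.na(out)] <- "."
    out
  }
  lines <- c(paste0("#", paste(.CONSENSUS_COLS, collapse = "\t")),
             if (nrow(cn)) do.call(paste,
               c(lapply(cn[.CONSENSUS_COLS], fmt), sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' Read SNV calls from a VCF file
#'
#' Reads a VCF 4.x file (e.g. VarScan2 output) into a [CallSet-class]. Only
#' single-nucleotide records are kept; indel records are skipped and counted
#' in the metadata. Field mapping, first sample column: coverage from
#' \code{DP} (FORMAT, else INFO), variant allele count from \code{AD}
#' (last entry when comma-separated), frequency from \code{FREQ}
#' (\code{"30\%"} style) else \code{AD/DP}, quality from \code{ABQ} (else
#' \code{BQ}), p-value from \code{PVAL} (FORMAT or INFO). Missing fields are
#' NA, never zero. Genotype comes from \code{GT} when present, otherwise it
#' is inferred as homozygous variant when \code{vaf >= 0.75} and
#' heterozygous ref/variant below that.
#'
#' Multi-allelic records keep the first ALT allele (per-allele depths beyond
#' the primary alternate are not consumed); their count is recorded in the
#' metadata.
#'
#' @param path path to a VCF file.
#' @param sampleId,replicateId identifiers for the resulting CallSet.
#' @return a [CallSet-class] (no consensus table).
#' @export
readVcfCalls <- function(path, sampleId = "sample",
                         replicateId = basename(path)) {
  vcf <- tryCatch(
    VariantAnnotation::readVcf(path, genome = "unknown"),
    error = function(e) stop("malformed VCF ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altList <- VariantAnnotation::alt(vcf)
  nAlt <- lengths(altList)
  alt1 <- rep(NA_character_, length(ref))
  alt1[nAlt > 0] <- vapply(altList[nAlt > 0],
                           function(a) as.character(a[1]), character(1))
  isSnv <- nchar(ref) == 1L & !is.na(alt1) & nchar(alt1) == 1L &
    ref %in% .BASES & alt1 %in% .BASES
  nSkipped <- sum(!isSnv)
  nMulti <- sum(nAlt > 1L & isSnv)
  if (nSkipped)
    message(path, ": skipped ", nSkipped, " non-SNV record(s)")

  getGeno <- function(field) {
    g <- VariantAnnotation::geno(vcf)
    if (field %in% names(g)) g[[field]][, 1] else NULL
  }
  getInfo <- function(field) {
    i <- VariantAnnotation::info(vcf)
    if (field %in% names(i)) {
      x <- i[[field]]
      if (is.list(x) || methods::is(x, "List"))
        x <- vapply(x, function(e) if (length(e)) as.character(e[1])
                    else NA_character_, character(1))
      x
    } else NULL
  }
  num <- function(x) if (is.null(x)) NULL else suppressWarnings(
    as.numeric(vapply(as.character(x), function(s) {
      if (is.na(s)) return(NA_character_)
      utils::tail(strsplit(s, ",")[[1]], 1)
    }, character(1), USE.NAMES = FALSE)))

  n <- length(ref)
  coverage <- num(getGeno("DP"))
  if (is.null(coverage)) coverage <- num(getInfo("DP"))
  if (is.null(coverage)) coverage <- rep(NA_real_, n)
  vac <- num(getGeno("AD"))
  if (is.null(vac)) vac <- rep(NA_real_, n)
  freq <- getGeno("FREQ")
  vaf <- if (!is.null(freq)) {
    suppressWarnings(as.numeric(sub("%$", "", as.character(freq)))) / 100
  } else vac / coverage
  if (is.null(vaf)) vaf <- rep(NA_real_, n)
  vaq <- num(getGeno("ABQ"))
  if (is.null(vaq)) vaq <- num(getGeno("BQ"))
  if (is.null(vaq)) vaq <- rep(NA_real_, n)
  pvalue <- num(getGeno("PVAL"))
  if (is.null(pvalue)) pvalue <- num(getInfo("PVAL"))
  if (is.null(pvalue)) pvalue <- rep(NA_real_, n)

  gt <- getGeno("GT")
  genotype <- rep(NA_character_, n)
  hetInferred <- is.na(vaf) | vaf < 0.75
  for (i in which(isSnv)) {
    g <- if (!is.null(gt)) gt[i] else NA_character_
    genotype[i] <- if (!is.na(g) && grepl("^[01][/|][01]$", g)) {
      a <- as.integer(substr(g, 1, 1))
      b <- as.integer(substr(g, 3, 3))
      genotypeString(ifelse(a == 0, ref[i], alt1[i]),
                     ifelse(b == 0, ref[i], alt1[i]))
    } else if (hetInferred[i]) {
      genotypeString(ref[i], alt1[i])
    } else {
      genotypeString(alt1[i], alt1[i])
    }
  }

  variants <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = ref, genotype = genotype, variantAllele = alt1,
    coverage = coverage, vac = vac, vaf = vaf, vaq = vaq, pvalue = pvalue,
    stringsAsFactors = FALSE)[isSnv, , drop = FALSE]
  # hom-ref genotypes (e.g. GT=0/0) carry no variant; drop them
  homRef <- !is.na(variants$genotype) &
    variants$genotype == paste0(variants$ref, variants$ref)
  variants <- variants[!homRef, , drop = FALSE]
  CallSet(sampleId, replicateId, variants = variants,
          metadata = list(inputRows = n, skippedRows = nSkipped,
                          multiAllelic = nMulti))
}

#' Read target regions from a BED file
#'
#' BED intervals (0-based, half-open) are converted to 1-based, fully closed
#' coordinates matching the call tables.
#'
#' @param path path to a BED file.
#' @return data.frame with columns chrom, start, end (1-based closed).
#' @export
readBedTargets <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Read a windowed GC-content track
#'
#' Expects a tab-separated table with columns \code{chrom start end
#' gc_fraction} (header optional, \code{#}-prefixed or plain); windows are
#' 0-based half-open as in BED.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns chrom, start, end, gc_fraction.
#' @export
readGcTrack <- function(path) {
  lines <- readLines(path)
  if (length(lines) && grepl("^#?chrom", lines[1])) lines <- lines[-1]
  df <- utils::read.table(text = lines, sep = "\t",
                          col.names = c("chrom", "start", "end",
                                        "gc_fraction"),
                          stringsAsFactors = FALSE)
  if (any(df$gc_fraction < 0 | df$gc_fraction > 1))
    stop("gc_fraction outside [0, 1]")
  df
}

#' Look up GC content at positions from a windowed track
#'
#' @param track data.frame from [readGcTrack()].
#' @param chrom,pos position vectors (1-based).
#' @return numeric vector of gc_fraction values, NA outside all windows.
#' @export
gcAt <- function(track, chrom, pos) {
  out <- rep(NA_real_, length(pos))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    tr <- track[track$chrom == ch, , drop = FALSE]
    if (!nrow(tr)) next
    tr <- tr[order(tr$start), , drop = FALSE]
    # 1-based pos p lies in 0-based window [start, end) iff start < p <= end
    idx <- findInterval(pos[sel] - 1L, tr$start)
    ok <- idx >= 1L & pos[sel] <= tr$end[pmax(idx, 1L)]
    out[sel][ok] <- tr$gc_fraction[idx[ok]]
  }
  out
}

#' Flag high-functional-importance (HFI) variants
#'
#' A variant is HFI when its functional-impact class is high or medium, or
#' when it is a stopgain (nonsense) or stoploss change. Unknown or missing
#' annotation fields yield FALSE.
#'
#' @param object a [CallSet-class] or a variant data.frame.
#' @return logical vector, one flag per variant.
#' @examples
#' classifyHfi(data.frame(maCategory = c("medium", "low", NA),
#'                        exonicClass = c(NA, "synonymous", "stopgain")))
#' @export
classifyHfi <- function(object) {
  v <- if (methods::is(object, "CallSet")) variantCalls(object) else object
  ma <- if ("maCategory" %in% names(v)) v$maCategory else
    rep(NA_character_, nrow(v))
  ec <- if ("exonicClass" %in% names(v)) v$exonicClass else
    rep(NA_character_, nrow(v))
  (!is.na(ma) & ma %in% c("high", "medium")) |
    (!is.na(ec) & ec %in% c("stopgain", "stoploss"))
}
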