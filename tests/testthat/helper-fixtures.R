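# fixtures are built in code: small call sets, consensus tables and VCF text

makeCallSet <- function(sample, rep, pos, genotype, ref = "A",
                        coverage = 100L, vac = 40L, vaf = 0.4, vaq = 25,
                        pvalue = 0, chrom = "chr1", ...) {
  n <- length(pos)
  recycle <- function(x) rep_len(x, n)
  v <- data.frame(chrom = recycle(chrom), pos = as.integer(pos),
                  ref = recycle(ref), genotype = recycle(genotype),
                  coverage = as.integer(recycle(coverage)),
                  vac = as.integer(recycle(vac)),
                  vaf = recycle(vaf), vaq = recycle(vaq),
                  pvalue = recycle(pvalue), stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) v[[nm]] <- recycle(extra[[nm]])
  v$vac <- pmin(v$vac, v$coverage)
  v$variantAllele <- mapply(function(g, r) {
    a <- substr(g, 1, 1); b <- substr(g, 2, 2)
    if (a != r) a else b
  }, v$genotype, v$ref)
  CallSet(sample, rep, variants = v)
}

# independent brute-force oracle for the SNV concordance rate: a plain
# position-by-position double loop, sharing no code with snvConcordance
bruteForceRc <- function(a, b) {
  va <- variantCalls(a)
  vb <- variantCalls(b)
  nc <- 0L
  for (i in seq_len(nrow(va))) {
    for (j in seq_len(nrow(vb))) {
      if (va$chrom[i] == vb$chrom[j] && va$pos[i] == vb$pos[j] &&
          !is.na(va$genotype[i]) && !is.na(vb$genotype[j]) &&
          va$genotype[i] == vb$genotype[j])
        nc <- nc + 1L
    }
  }
  nc / mean(c(nrow(va), nrow(vb)))
}

randomCallSetPair <- function(maxPos = 50L) {
  mkOne <- function(r) {
    n <- sample.int(maxPos, 1L)
    pos <- sample.int(200L, n)
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt <- vapply(ref, function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1L), character(1))
    geno <- ifelse(runif(n) < 0.5, genotypeString(ref, alt),
                   genotypeString(alt, alt))
    makeCallSet("rnd", r, pos, geno, ref = ref)
  }
  list(a = mkOne("r1"), b = mkOne("r2"))
}

writeConsensusFixture <- function(path, rows) {
  writeLines(c("#chrom\tpos\tref\tcall\tcoverage\tvac\tvaf\tvaq\tpvalue",
               rows), path)
}

vcfFixtureText <- function() {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=AD,Number=1,Type=Integer,Description=\"Variant depth\">",
    "##FORMAT=<ID=FREQ,Number=1,Type=String,Description=\"Frequency\">",
    "##FORMAT=<ID=ABQ,Number=1,Type=Integer,Description=\"Avg qual\">",
    "##FORMAT=<ID=PVAL,Number=1,Type=String,Description=\"P-value\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", sep = "\t"),
    paste("chr1", "100", ".", "A", "G", ".", "PASS", ".",
          "GT:DP:AD:FREQ:ABQ:PVAL", "0/1:100:30:30%:28:0.01", sep = "\t"),
    paste("chr1", "250", ".", "C", "T", ".", "PASS", ".",
          "GT:DP:AD:FREQ:ABQ:PVAL", "1/1:80:76:95%:31:0", sep = "\t"),
    paste("chr1", "300", ".", "G", "GA", ".", "PASS", ".",
          "GT:DP:AD:FREQ:ABQ:PVAL", "0/1:60:20:33.33%:25:0.02", sep = "\t"),
    paste("chr2", "50", ".", "T", "A", ".", "PASS", ".",
          "GT:DP:AD:FREQ:ABQ:PVAL", "0/1:40:10:25%:22:0.04", sep = "\t"))
}

simPair <- function(seed, ...) {
  sim <- simulateReplicateSet(simulationConfig(seed = seed, ...),
                              consensusMode = "variant")
  callSets(sim$replicateSet)
}
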