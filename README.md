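# ReplicateConcordance

Quantifies the technical reproducibility of single-nucleotide variant
(SNV) calls when the same genomic DNA is sequenced more than once. When a
sample is re-sequenced from library preparation onward, every disagreement
between the replicate call sets is technical noise; the replicate
concordance rate and the factors that predict it are the practical handle
on variant-calling specificity. The package is aimed at anyone running
targeted or exome sequencing with technical replicates who wants to know
how much of a call set to trust, and which quality thresholds actually
help.

## The statistic

For a replicate pair with $N_1$ and $N_2$ SNV calls, of which $N_c$ are
called in both replicates with identical genotype,

$$R_c = \frac{N_c}{\mathrm{mean}(N_1, N_2)}.$$

Triplicates are summarised by the unweighted mean of the three pairwise
rates. Around this core the package provides:

- whole-region concordance over consensus nucleotide calls, with or
  without ambiguous `N` positions (`allcallConcordance`);
- concordance stratified by coverage depth, variant allele count (VAC),
  variant allele frequency (VAF), variant allele quality (VAQ), SNV-call
  p-value, substitution type, genome annotation and GC content, under a
  same-bin pairing rule with Sturges or empirical binning
  (`concordanceByFactor`, `sturgesBins`, `mergeTailBins`);
- factor-importance ranking by mutual information, univariate-logistic
  AIC and L1-penalised logistic entry order (`associationSummary`,
  `lassoEntryOrder`);
- threshold-filter evaluation with shipped presets and paired
  before/after testing (`applyFilter`, `filterEffect`,
  `categorizedCriteria`, `pooledPreset`);
- a seeded synthetic replicate generator with ground-truth labels
  (`simulateReplicateSet`), so the whole pipeline is testable without
  controlled-access data;
- readers for VCF call sets, consensus-call tables, BED targets and GC
  tracks (`readVcfCalls`, `readConsensusTable`, ...).

See the vignette `vignettes/replicate-concordance-methods.Rmd` for the
model, conventions and design choices.

## Worked example

Simulate one duplicated sample under study-like conditions and run the
core analyses:

```r
library(ReplicateConcordance)

sim <- simulateReplicateSet(simulationConfig(seed = 7),
                            consensusMode = "variant")
rs <- sim$replicateSet
replicateConcordance(rs)
#> ConcordanceResult: Nc=424 N1=588 N2=645 Rc=0.6878

pooled  <- poolStatus(rs)
schemes <- buildFactorSchemes(pooled)
associationSummary(pooled, schemes)[, c("factor", "mutual_information",
                                        "aic", "lasso_entry_rank")]
#>     factor mutual_information  aic lasso_entry_rank
#> 1 coverage             0.0105 1119                5
#> 2      vac             0.5717  328                4
#> 3      vaf             0.4962  359                1
#> 4      vaq             0.1715  861                3
#> 5   pvalue             0.2362  774                2
```

The pair reproduces 424 of roughly 600 calls ($R_c$ = 0.69, squarely in
the 0.53–0.73 range observed for real replicated kinome data). The
importance ranking recovers the planted structure: VAC carries the most
mutual information and the lowest AIC, VAF enters the lasso path first,
and coverage — informative only through its correlation with VAC — enters
last.

The package also ships the published per-pair concordance counts of a
17-sample replicated kinome study as a reference table:

```r
summ <- summarizeCountTable(kinomeReplicateCounts())
head(summ$perSample[, c("sample_id", "replicate_type", "snv_pct",
                        "allcall_pct")], 4)
#>   sample_id replicate_type snv_pct allcall_pct
#> 1       294            Dup    64.4     99.9919
#> 2       339            Dup    68.2     99.9902
#> 3       494            Dup    68.1     99.9899
#> 4       506            Dup    52.7     99.9905
```

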