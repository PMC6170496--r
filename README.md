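# methTAR

Whole-genome bisulfite sequencing (WGBS) analysis of **transgenerational
acquired resistance (TAR)**: when plants such as *Arabidopsis* are repeatedly
exposed to disease, their progeny — sometimes several stress-free generations
later — show enhanced resistance, and the question is whether and how that
phenotype is mirrored in heritable cytosine methylation. methTAR implements
the complete desk-side analysis for pedigree-structured WGBS studies of this
kind, from per-cytosine count tables to the downstream set-algebra arguments,
together with a generative simulator so that every stage can be validated
without sequencing data.

It is aimed at plant epigenomics groups running multi-generation
stress-pedigree experiments (mock- vs pathogen-inoculated lines propagated by
single-seed descent, with pooled-plant replicate samples) and at
methodologists who want a testable reference implementation of this analysis
chain.

## What it computes

**Per-position differential methylation.** For two groups of pooled samples
with replicate counts (M methylated of C reads at each cytosine), the default
test models counts as beta-binomial. The effect size is the coverage-pooled
fraction difference Δ = p̂_t − p̂_c with group variance

    Var(p̂_g) = p(1−p) · Σᵢ Cᵢ(1 + (Cᵢ − 1)φ) / (Σᵢ Cᵢ)²,

where the per-position dispersion φ is a Williams-type method-of-moments
estimate shrunk toward an empirical prior across positions (precision
weighting on the log scale). The Wald statistic Δ/√(Var_t + Var_c) is
referred to the standard normal, and q-values are Benjamini–Hochberg per
sequence context (CG/CHG/CHH); DMPs are positions with q below the FDR
threshold (default 5%). A logistic-regression backend (binomial GLM with a
quasi-likelihood scale factor) is provided as a cross-check, and DMRs are
segmented from relaxed per-position cut-offs (p < 0.01, |Δ| ≥ 0.1) with a
minimum regional difference of 10%.

**Sample structure.** Hierarchical clustering of percent-methylation
profiles on 1 − Pearson correlation with Ward linkage, after removing
positions with below-median standard deviation; edge confidence by
multiscale bootstrap (resampling positions at ten scales, WLS fit of the
normal-quantile transform) giving AU (approximately unbiased) and BP
(bootstrap probability) supports, plus centered PCA.

**Set algebra of DMP catalogues.** Direction-aware intersection of two
comparisons sharing a control (a DMP is *shared* only if the direction
agrees; opposite-direction positions count in both only-sections),
dose-intensity classification of shared DMPs (≥ 20 percentage-point
difference of effect between dose arms, direction-aware), in silico removal
of a position set followed by re-clustering with a treatment-clade verdict,
overlap of DMP sets with a labile/stable position catalogue (Fisher's exact
2×2 shift test), and same-direction overlap percentages between independent
experiments.

**Everything around the statistics.** Bismark-style cytosine report IO with
coverage filtering (mincov, upper-percentile), median-of-medians coverage
normalisation, symmetric-CG destranding, group-wise uniting with
missingness, bisulfite conversion-rate estimation from unmethylated
chloroplast DNA, 100-bp window tiling, transposon > gene > intergenic
feature annotation (GFF3/BED), and exact r×c tests with FDR-adjusted
all-versus-all comparisons and compact-letter displays for *Hpa*
colonisation-class resistance assays.

**Simulator.** `simulate_study()` generates pedigree-structured methylomes:
diploid three-state epialleles, spontaneous epimutation concentrated at
labile CG positions, a heritable stress dose that accumulates additively per
stressed generation and is expressed per pooled plant with a penetrance,
pools of 10 plants, negative-binomial coverage and imperfect bisulfite
conversion, with truth tables for every downstream check.

## Worked example

Simulate a second-F3-style pedigree (mock MMM, single-generation stress SMM,
triple-stress SSS; three pooled replicates each), run the pipeline, and ask
the two headline questions — is the shared differential methylation
dose-dependent, and do replicate samples cluster by line?

```r
library(methTAR)

model <- epigenome_model(n_cg = 3000, n_chg = 300, n_chh = 300,
                         n_chloroplast = 1000, n_stress_responsive = 400,
                         seed = 11)
ped <- pedigree(c(MMM = "MMM", SMM = "SMM", SSS = "SSS"), replicates = 3)
sim <- simulate_study(ped, model)

estimate_conversion(attr(sim$samples[[1]], "control"))
#> [1] 0.9944581

tabs <- normalize_coverage(lapply(sim$samples,
                                  function(t) destrand_cg(filter_by_coverage(t))))
united <- unite_samples(tabs, groups = sub("_[0-9]+$", "", names(sim$samples)),
                        min_per_group = 2, context = "CG")

dmps_sss <- call_dmps(united, treatment = "SSS", control = "MMM")
dmps_sss
#> DMP call (wald backend, SSS vs MMM): 2999 positions tested, 403 DMPs at q < 0.05
#>      hyper hypo
#>   CG   216  187

dmps_smm <- call_dmps(united, treatment = "SMM", control = "MMM")
sss <- as_dmp_set(dmps_sss, "SSS-vs-MMM")
shared <- add_partner_deltas(
  intersect_dmps(as_dmp_set(dmps_smm, "SMM-vs-MMM"), sss), sss)
shared
#> Shared-DMP summary: SMM-vs-MMM vs SSS-vs-MMM
#>   shared (same direction): 107  [hyper 50/222 = 22.5%; hypo 57/192 = 29.7%]
#>   only-sections: 11 + 296 (sum 307; 0 opposite-direction counted in both; 307 unique)

dose_intensity(shared, threshold = 20)
#> Dose intensity (threshold 20 pp):
#>   more pronounced in high dose: 37 hyper, 39 hypo
#>   more pronounced in low dose:  0 hyper, 1 hypo
#>   neither: 30; excluded (missing delta): 0

x <- filter_low_variation(percent_matrix(united))
tree <- multiscale_bootstrap(x, nboot = 200, seed = 1)
clade_support(tree, grep("^SSS", colnames(x), value = TRUE))
#> $is_clade
#> [1] TRUE
#> $au
#> [1] 100
#> $bp
#> [1] 100
```

The conversion estimate recovers the simulated 99.5% bisulfite conversion
from chloroplast reads. The SSS-vs-MMM call finds ~400 CG DMPs — the
simulator placed 400 stress-responsive positions. Of the DMPs shared with
the weaker SMM comparison, 76 are ≥ 20 points stronger in the
thrice-stressed line against 1 in the once-stressed line: the additive dose
effect the design encodes. The three SSS replicates form an exclusive clade
with full AU/BP support; `plot(tree)` draws the dendrogram with supports and
`as_newick(tree)` exports it.

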