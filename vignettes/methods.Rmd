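---
title: "Models and methods behind methTAR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind methTAR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methTAR)
```

methTAR analyses whole-genome bisulfite data from multi-generation
stress-pedigree experiments: lines propagated by single-seed descent, each
generation either mock-treated (M) or pathogen-stressed (S), with the final
generation sequenced as pooled replicate populations. This vignette is the
package's own account of the statistical choices involved — the models, the
defaults and why, what the simulator does and does not emulate, and the
places where the design was genuinely open.

## 1. Count model and the position test

A sample's record at a cytosine is a pair (M, C): methylated calls out of C
reads. Within a group of replicate pooled samples we model M ~
beta-binomial(C, p, φ): the pool-to-pool variation of the true methylation
fraction (different plants, different penetrance of any heritable effect)
over-disperses counts relative to the binomial, and ignoring it is
anti-conservative — the suite demonstrates this by forcing φ = 0 on
over-dispersed null data and watching the false-call rate inflate.

**Dispersion.** Per position, a Williams-type method-of-moments estimator:
with group proportion p̂ = ΣM/ΣC, the statistic Σ(M − Cp̂)²/(Cp̂(1−p̂)) has
expectation (n−1)(1 + (C̄−1)φ) under the beta-binomial; solving, pooling the
two groups, gives a raw φ per position. Raw values from 4–8 replicates are
extremely noisy, so they are shrunk toward an empirical prior fitted across
positions: a log-normal fit on log(φ + 10⁻³) supplies the between-position
variance τ², the prior mean is moment-matched on the raw scale (keeping the
ensemble mean unbiased), and each position gets weight w = τ²/(τ² + σᵢ²)
with σᵢ² ≈ 2/(nᵢ − 2) the approximate log-scale sampling variance. Two
limits matter and are tested: with identical data at every position the
prior variance vanishes and shrinkage is total (equal to every raw value);
with heterogeneous positions the shrunk value always lies between the raw
estimate and the prior mean.

**Wald test.** The effect is the coverage-pooled difference Δ = p̂_t − p̂_c;
each group mean is a coverage-weighted average of replicate proportions, so
its variance is p(1−p)·ΣC(1 + (C−1)φ)/(ΣC)². The statistic Δ/√(v_t + v_c)
is referred to N(0,1), two-sided. At boundary proportions (p̂ ∈ {0,1}) the
variance is computed with 0.5 pseudo-counts added to the group totals —
variance only, never the estimate — so boundary positions get finite,
non-zero standard errors. With φ = 0 the statistic reduces exactly to the
unpooled two-proportion z-test on the summed counts (asserted analytically
in the tests).

**Logistic backend.** Because single-position group comparisons are also
commonly run as binomial regression, a second backend fits
`glm(cbind(M, U) ~ group, binomial)` per position and divides the squared
group-coefficient z by a quasi-likelihood scale (Pearson χ²/df), referring
the result to χ²(1). The scale is left unfloored — an underdispersed fit
genuinely sharpens the statistic under this convention — except under
complete separation (a group entirely at 0 or 1), where 0.5 pseudo-counts
per replicate are added and the scale is floored at 1 so the adjusted fit's
near-zero residuals cannot inflate the statistic. The two backends share the
Δ definition, so directions agree identically; the suite checks ≥ 95%
significance-call concordance on a mixed panel and cross-validates p-values
on the evidence (log₁₀) scale.

**Multiplicity.** Benjamini–Hochberg within each sequence context and
comparison: CG, CHG and CHH populations differ in size and signal by orders
of magnitude, and pooling them would let the dense CG signal distort non-CG
q-values.

**DMRs.** The region caller takes positions passing a relaxed cut (p < 0.01
and |Δ| ≥ 0.1), splits them by direction, merges neighbours closer than
100 bp, and keeps regions with ≥ 3 qualifying positions, span ≥ 50 bp,
≥ 50% of member positions qualifying and |mean Δ| ≥ 0.10 over all member
positions. The merge parameters are not dictated by any source and are
exposed as arguments; the direction split prevents opposite-signed
positions from cancelling inside one region.

## 2. Clustering and edge support

Samples are clustered on d = 1 − Pearson correlation of percent-methylation
profiles with Ward linkage (the Lance–Williams "ward" update applied to
these dissimilarities, i.e. `hclust(method = "ward.D")`), after discarding
positions whose across-sample standard deviation is strictly below the
median — ties at the median are kept, so a degenerate all-equal matrix
passes through intact. Correlations use pairwise-complete positions; PCA,
which needs a complete matrix, uses complete cases only. This divergence is
deliberate: pairwise-complete keeps the distance estimates efficient under
scattered missingness, while PCA on pairwise-imputed covariances can lose
positive-definiteness. Columns are ordered lexicographically by sample id
before clustering so that ties break deterministically.

Edge confidence comes from multiscale bootstrap: positions are resampled
with replacement at relative sizes r ∈ {0.5, …, 1.4} (ten scales), the tree
is rebuilt `nboot` times per scale, and each reference edge's recovery
frequency BP_r is recorded. Per edge, qnorm(1 − BP_r) is regressed on
(√r, 1/√r) by weighted least squares with binomial weights; the fitted
signed distance v and curvature c give AU = 1 − Φ(v − c). BP is reported at
r = 1. Each scale's resampling stream is seeded from (seed, r), which makes
the reported BP definitionally identical to a plain bootstrap run at r = 1
with the same seed — a property the suite asserts. Edges with degenerate
BP traces (all 0 or all 1) short-circuit to 0 or 100. `nboot` defaults to
10,000 to match common practice for publication figures; the tests and the
acceptance script use 150–300, which is enough for the binary verdicts they
check, and values below 100 trigger a degraded-estimate warning.

A "treatment clade verdict" asks whether a named sample set forms an
exclusive clade and reports that edge's AU; downstream checks count the
grouping as supported only when the clade exists *and* AU ≥ 95 — a clade
that merely appears in the point-estimate tree of a noise matrix is not
evidence.

## 3. Set algebra

The shared-DMP intersection is direction-aware: a position significant in
both comparisons but hyper-methylated in one and hypo in the other is *not*
shared; it is counted in both only-sections. Consequently
`section_sum = |a_only| + |b_only|` double-counts those positions and
`unique_union = section_sum − n_opposite` is the distinct non-shared count —
an invariant property-tested on random sets. Shared percentages are
reported per direction as a fraction of the per-direction union, rounded
half-up to one decimal (the house reporting style; `round_half_up()` exists
because R's `round()` is banker's).

"More pronounced" in the dose comparison is a signed difference-of-deltas:
a hyper DMP is more pronounced in the high-dose arm iff
Δ_high − Δ_low ≥ 20 percentage points, a hypo DMP iff the same holds for
−Δ. No source formula exists for this; the signed, direction-specific
reading is the one under which "more pronounced" means "further in the
DMP's own direction", and both the threshold and the rule are arguments.
The paired (Δ_low, Δ_high) table is returned for plotting; the natural plot
is Δ_high against Δ_low, not either delta against the control line.

Removal re-clustering deletes a position set from the united matrix and
re-runs the clustering with the same seed stream, reporting the clade
verdict before and after plus bookkeeping: removal positions absent from
the table are counted, and with `match = "cg_pair"` a destranded CG
coordinate removes its strand partner record at pos + 1 as well (destranded
tables can retain unpaired minus-strand records, so entries removed can
slightly exceed the removal-set size — the source of small discrepancies
between naive subtraction and reported table sizes in this kind of
analysis).

The lability-overlap test cross-tabulates a DMP set and a comparator set
against labile/stable position classes and applies a two-sided Fisher exact
test to the 2×2; the exact statistic for the published shift claim is not
named anywhere, and Fisher on the 2×2 is the implemented choice.

## 4. Resistance assay statistics

Colonisation-class tables (lines × ordinal severity classes I–IV) are
compared with the exact conditional r×c test (two-sided by the standard
convention: total probability of margin-fixed tables no more probable than
the observed one), all-versus-all, with BH adjustment across the pairs of
one figure — whether the published analyses pooled adjustment per figure or
per experiment is not stated; per-figure pooling is implemented. The
compact-letter display assigns one letter per maximal clique of the
non-significance graph (brute-force enumeration; line counts are single
digits), so two lines share a letter iff they are not significantly
different.

## 5. The simulator: what it emulates, and what it does not

`simulate_study()` generates the full study: a common founder epigenome; per
line, one germline individual per generation receiving that generation's
treatment; per replicate, a pool of `pool_size = 10` stress-free offspring
of the final individual; per sample, a Bismark-style count table plus truth
tables (responsive positions with directions, labile/stable classes,
per-line expected shifts).

**Epialleles.** Diploid three-state model: 0, 0.5, 1 (neither/one/both
alleles methylated) — the simplest state space that yields quantitative
population fractions from discrete inheritance. Spontaneous epimutation
moves one state step per event, with per-generation probabilities
`eps_labile = 0.003` at labile sites (default 20% of CG sites) and
`eps_stable = 1e-4` elsewhere. These are free parameters of the simulator,
documented as such — they are not estimates of published mutation-
accumulation rates, and nothing downstream depends on their exact values.

**Stress.** `n_stress_responsive` CG sites (default 4% of sites, 75% drawn
from the labile class, mirroring the observation that heritable stress
effects concentrate on labile positions but extend beyond them) carry a
designated direction; hyper-responsive sites start unmethylated, hypo start
methylated. Each stressed generation adds `delta_stress = 0.15` to a
heritable germline dose at every responsive site — deterministically, so
the dose is exactly additive and the truth tables satisfy
E[p_SSS − p_MMM] = 3·E[p_SMM − p_MMM] by construction. At pooling time each
plant expresses the accumulated dose with probability `penetrance = 0.8`;
an expressing plant realises the dose as whole epiallele steps by
stochastic rounding (dose 0.45 → one 0.5-step with probability 0.9),
clipped to [0, 1]. An earlier design drew the stress steps as independent
per-generation Bernoulli flips in each line; that made realised shifts
nearly uncorrelated across independently stressed lines, and their samples
failed to co-cluster — contradicting the very phenomenon the pipeline is
meant to detect — so the deterministic-dose/penetrance split was adopted:
heritable and consistent across lines, quantitative at the population level
through penetrance and pooling. Penetrance at the plant level also
reproduces a realistic failure mode: occasionally a replicate pool draws
few expressing plants and becomes a methylome outlier, exactly the kind of
sample a real study flags in QC.

**Reads.** Coverage per strand record is negative-binomial (mean 20,
dispersion 0.3 — typical WGBS depth after filtering); methylated counts are
binomial in the *apparent* fraction p′ = p + (1 − p)(1 − c) with bisulfite
conversion `c = 0.995` (the published per-sample range is roughly
99.4–99.6%), and the chloroplast contig ChrC carries truly unmethylated
control cytosines from which `estimate_conversion()` recovers c. CG sites
emit both strand records (plus at x, minus at x + 1) so destranding is
exercised by simulated data; CHG/CHH positions get fixed population
fractions shared by all lines — no heritable non-CG dynamics — which
reproduces the qualitative observation that treatment structure appears in
CG and not in non-CG contexts, but means the simulator cannot probe non-CG
inheritance models.

**Reproducibility.** One global seed; every line, sample and bootstrap
scale draws from a substream derived deterministically from (seed, keys),
so runs are byte-identical and per-sample streams are independent of
enumeration order.

**What passing tests do and do not show.** The generator produces iid
noise around a block-structured signal with exactly additive dose and no
genomic autocorrelation, sequence-context composition, mappability
structure, TE mobilisation or DNA mutation. Tests passing on it validate
the statistical machinery — error control under over-dispersion, recovery
of planted effects, the set-algebra identities, the clustering verdicts —
not the biological fidelity of any real dataset.

## 6. Numerical and bookkeeping choices

- Coordinates are 1-based with inclusive endpoints everywhere (Bismark
  convention); bedGraph/BED exports convert to 0-based half-open and the
  converters are tested.
- The coverage percentile filter uses linear interpolation between order
  statistics (`quantile` type 7); no source specifies a definition, so one
  is fixed and documented.
- Coverage normalisation scales M and U separately by the
  median-of-medians factor and rounds each half-up; a record whose coverage
  would vanish keeps coverage 1 with the majority call. (An alternative
  convention — round M and C, then U = C − M — gives different third
  decimals; the M/U convention matches the worked arithmetic this package
  standardises on.)
- United tables keep missing entries as NA, never 0: absence of coverage is
  not evidence of absence of methylation.
- `tile_windows` sums counts NA-aware; a window is missing for a sample
  only if no member position is covered.
- Degenerate inputs fail loudly: empty pools, zero-coverage groups,
  zero-margin contingency rows (dropped with a warning), samples with zero
  variance in correlation clustering.

## 7. Problem sizes

The shipped tests and the acceptance script run the full pipeline at
desk scale, chosen so each behaviour is measured with comfortable margin:
null error control on 20,000 positions across φ ∈ {0, 0.05, 0.15};
dispersion recovery on 5,000 positions; sensitivity on a 5,000-site
one-generation pedigree with 200 responsive sites at a 0.4 shift, coverage
20, three replicates; the clustering contrast and removal experiment on
8,000-site pedigrees with 960 responsive sites (the clade-support verdict
needs a few thousand retained positions before position-resampling noise
stops dominating the edge supports — at a few hundred positions AU for a
true 6-sample clade fluctuates widely, which is a scaled-down artifact, not
a property of the method); dose monotonicity on a 3,000-site MMM/SMM/SSS
pedigree. The two clustering scenario datasets are generated from fixed
seeds, because their outputs are binary verdicts; all other randomness
follows the caller's seed.

## 8. Known limitations

- The Wald test's normal reference is approximate at three replicates per
  group and coverage ~20; the suite verifies control of the *false-call
  fraction* after BH, not exact per-position type-I calibration in the
  extreme tail.
- AU values are extrapolations; for edges whose BP is near 0 or 1 at every
  scale the WLS fit is skipped and the support saturates to 0/100.
- No covariate adjustment, paired designs or copy-number-aware correction
  in the position test; no promoter logic beyond a configurable upstream
  window in the annotation module; no read-level or alignment-level
  processing — the pipeline starts at cytosine count tables.
- Per-sample QC is exposed (coverage summaries, conversion rates, tree
  positions) but nothing is auto-discarded; outlier replicates are the
  analyst's call.
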