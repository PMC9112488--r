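---
title: "Methods: proteomic-ruler quantification and downstream statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteomic-ruler quantification and downstream statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protruler)
```

This vignette documents the models and procedures the package implements,
the assumptions behind them, the tunable parameters and their defaults,
what the synthetic-data generator does and does not emulate, and the
numerical and design choices made where several readings were possible.

## 1. The histone proteomic ruler

Label-free quantification (LFQ) intensities are proportional to protein
mass within a run but carry an arbitrary overall scale. The proteomic
ruler removes that scale by exploiting a biological constant: chromatin
packages genomic DNA with core histones at a roughly 1:1 mass ratio, and
the DNA mass per cell is fixed by the genome. With

* `genome_size_bp` = 3.1e9 bp (haploid human genome),
* `bp_molar_mass` = 615.8771 g/mol per base pair,
* `ploidy` = 2 (default),
* `avogadro` = 6.02214076e23 /mol,

the DNA mass per cell is `m_DNA = ploidy * genome_size_bp * bp_molar_mass
/ avogadro` ≈ 6.34 pg. Equating the summed intensity of the core histones
`S_h` in a sample with `m_DNA` gives, per protein `i` with molecular
weight `MW_i` (Da):

* mass per cell: `m_i = I_i * m_DNA / S_h`,
* copies per cell: `c_i = (I_i / MW_i) * N_A * m_DNA / S_h`.

**Assumptions.** (i) LFQ intensity is proportional to protein mass with a
single per-sample constant; (ii) histone mass per cell equals DNA mass;
(iii) ploidy is known. Polyploid cells — hepatocytes carry one to four
nuclei — violate (iii) under the diploid default, and their copy numbers
are then underestimated; `ruler_constants(ploidy = ...)` overrides it per
cell type. Histones are flagged from an explicit identifier list (GMT;
see `core_histone_genes()`), never from name patterns, so the anchor set
is reproducible across identifier schemes.

**Contracts.** The ruler operates on raw, unimputed intensities only
(imputed values are a statistics device, not a quantification); missing
intensities yield missing copies; per sample, the summed protein mass
equals `m_DNA * ΣI / S_h` exactly; copies are invariant to global
intensity rescaling (bit-identical for power-of-two factors, to
floating-point resolution otherwise); copies scale exactly linearly in
ploidy.

Complex stoichiometry reports each subunit's copy ratio to the complex
mean with a within-`fold` flag (default `fold = 2`, i.e. ratio in
[0.5, 2]) plus complex copy totals; complexes with fewer than two
quantified members are reported as not evaluable rather than erroring,
since that is a data property, not a usage error.

## 2. Mass budgets

Class fractions count a protein fully in every class it belongs to
(classes overlap; columns need not sum to 100%). Compartment fractions
must close a whole-cell budget, and many proteins co-localize; the
default `equal_split` scheme divides a protein's mass evenly over its `k`
annotated compartments and routes unannotated proteins to "unassigned",
so fractions plus unassigned sum to exactly 100%. Whether mass should be
split equally or proportionally to localization evidence is not
determined by any input we consume; equal split is the explicit,
documented assumption, and `full_count` retains the unnormalized overlap
view. Cumulative-abundance ranking breaks ties lexicographically by
protein ID so the quartile counts are deterministic.

## 3. Filtering, imputation, and the two data views

Two validity filters are provided: a count rule (at least `t` valid
values in the replicates of at least one group — the atlas-style "2 of 3
in any cell type") and a fraction rule (at least a fraction valid in
*every* group — the strict reading of a cohort-level 70% criterion; the
lenient any-group variant is available via `per_group = FALSE`). Filters
only drop rows and are idempotent.

Missing LFQ values are predominantly missing-not-at-random: low-abundance
proteins fall below the detection limit. Imputation therefore draws from
a down-shifted normal per sample column — `Normal(mu - 1.8*sd,
(0.3*sd)^2)` with `mu`, `sd` the observed column moments (denominator
n-1) on the log2 scale. Draws come from one seeded stream ordered by
(sample, protein), so results are independent of storage order; observed
values are never modified; a column with fewer than two observed values
is an error because its s.d. is undefined.

The package maintains two strictly separated data views: detection-based
analyses (marker calling, pathway coverage) use pre-imputation validity;
parametric tests use the filtered, log2, imputed matrix. Imputed values
never count as detections.

## 4. Marker calling

Detection counts per protein and cell type feed a one-sided Fisher exact
test of the target type against all others pooled
(`[[det_t, n_t - det_t], [det_rest, n_rest - det_rest]]`, alternative
"greater"). One-sided because the criterion is enrichment of detection; a
two-sided test would also flag depleted proteins. Candidates require
detection in ≥ 2 target replicates, zero detections elsewhere, and
`p < 0.05` (strict inequality); with 3 target and 9 rest replicates the
all-vs-none pattern gives `p = 1/220` and the 2-of-3 pattern `3/66`, so
the conventional 0.05 cut admits exactly the "at least two of three"
patterns. Strict markers additionally require detection in *every* target
replicate. The screen is left uncorrected, as is conventional for this
detection-pattern criterion; BH-adjusted values are reported alongside
for reference.

## 5. Differential abundance

One-way ANOVA and ANCOVA (`log2 ~ group + age + sex`, partial F for the
group factor) are computed by vectorized least squares: the design is
shared by all proteins, so one QR decomposition per model evaluates every
protein's residual sum of squares at once. This is numerically identical
to per-protein `lm()`/`aov()` fits (verified against them in the tests)
and orders of magnitude faster at proteome scale. Rank-deficient designs
raise an error naming the aliased terms. Proteins with zero residual
variance are flagged `degenerate` and reported with `p = 0` (group means
differ) or `p = 1` (constant response), never silently dropped. BH
adjustment runs across all tested proteins; `significant` means
`q < fdr`.

Tukey post hoc comparisons run only on the omnibus-significant set: the
difference of covariate-adjusted group means over its model standard
error, referred to the studentized range distribution with the model's
residual df (Tukey–Kramer). The family is the `k(k-1)/2` pairs within a
protein; no second correction across proteins is applied, matching how
pairwise counts are conventionally reported downstream of an
FDR-controlled omnibus screen. The implementation matches
`stats::TukeyHSD` exactly in the covariate-free case and `emmeans`
pairwise Tukey p-values in the adjusted case.

Clustering z-scores per-protein group-mean profiles (flat profiles map to
zero vectors), then applies agglomerative hierarchical clustering with
Euclidean distance. Average linkage is the default — the linkage was a
genuinely open choice, and average linkage is the common default for
z-scored omics profiles — with the method exposed as an option. Cluster
IDs are relabeled by first appearance for determinism.

A per-protein equal-variance (Bartlett) and normality (Shapiro–Wilk on
within-group-centered residuals) screen is provided as a reported
diagnostic only; it does not gate any test.

## 6. Enrichment

Term enrichment is a one-sided hypergeometric test against an explicit,
user-supplied background — always the quantified set, never a
whole-genome default, because detection bias would otherwise enrich
everything highly expressed. Terms with fewer than 10 background members
are skipped (configurable), an optional fraction floor ("at least 10% of
the term in the foreground") is available, and BH control defaults to 1%
for term maps and 5% elsewhere. Ontology-graph traversal and term fusion
are out of scope; the test itself is the primitive.

## 7. The synthetic-data generator

The generator exists so that every downstream stage has ground truth. Its
defaults encode the study design the analysis targets:

| parameter | default | meaning |
|---|---|---|
| `n_proteins` | 2000 | protein groups (desk-scale proteome) |
| `cell_types` | 4 × 3 | hHEP/hLSEC/hHSC/hKC, 3 replicates each |
| `tissue_groups` | 3 × 6 | Liver/HepA/PorV, 6 replicates each |
| `cohort_groups` | 15/20/10 | control / NASH / cirrhosis samples |
| `log10_copy_mean`, `log10_copy_sd` | 4.0, 1.2 | log-normal copies/cell |
| `n_histones`, `histone_mass_fraction` | 8, 0.04 | ruler anchor |
| `noise_cv` | 0.20 | multiplicative measurement CV |
| `mnar_slope`, `mnar_quantile` | 0.3, 0.10 | detection-limit model |
| markers | 10 strict + 20 Fisher per type | cell-type-unique panels |
| `n_enriched_per_type`, `enriched_log2fc` | 50, 2 | characteristic blocks |
| `effect_fraction`, `effect_log2fc` | 0.10, 1.0 | cohort planted effects |
| `age_range`, `sex_balance` | 30–70, 0.5 | cohort covariates |

Abundances are log-normal (`log10 c ~ N(4, 1.2)`), independent across
proteins — wide enough that true copies span more than six decades, the
regime deep liver proteomes exhibit. Intensities are `I = k * c * MW *
eps` with `eps` log-normal of mean 1 and CV `noise_cv`, and `k` an
arbitrary per-run scale drawn from `10^U(-2, 2)` precisely so that any
analysis that is not scale invariant fails loudly. Histone copies are
fixed so total histone mass per cell equals `m_DNA` (the ruler anchor
holds exactly in truth), and one *global* rescale of non-histone copies
sets the histone share of total mass to 4% — global rather than per cell
type, because a per-type factor would act as a per-type intensity offset
and silently break the null for every protein. Total protein mass per
cell is therefore pinned near `6.34/0.04 ≈ 158` pg, within the 150–700 pg
range reported for liver cell types.

Missingness is applied after noise with probability
`plogis((midpoint - log10 I) / slope)`; by default the midpoint sits at
the 10th percentile of the generated log10 intensities (so the
detection-limit regime adapts to the arbitrary scale `k`), producing
~10–13% missing values concentrated in the low-abundance tail. Histone
rows are never masked: drop-out of the ruler anchor would make copies
undefined, which is an orthogonal failure mode to the ones the generator
is meant to exercise. Strict and Fisher-grade markers are planted with
zero copies outside their target cell type (structurally missing
intensities) and marker abundances of `10^N(5, 0.5)` copies — the
100k-copy scale of reported cell-type-specific proteins — which keeps
their per-replicate drop-out probability below ~1%.

Cell types share a common per-protein baseline; between-type differences
come only from planted markers and enriched blocks. This makes all
non-planted proteins an exact ANOVA null — which is what calibration
tests need — at the cost of the broad between-type divergence real cell
types show (pairwise proteome correlations of ~0.7–0.9 rather than ~1).
Passing tests therefore demonstrate correctness of the statistics on a
clean null plus planted alternatives, not robustness to diffuse
biological variation. Also not simulated: peptide-level structure,
retention time, batch effects, and any normalization failure between
runs.

The cohort generator works on the log2 scale directly: baseline
`log2(k * c * MW)`, a planted `+1` log2 shift in one randomly chosen
group for 10% of proteins, uniform age, balanced sex, optional age
confounding on a stated subset, Gaussian log2 noise matched to the 20%
CV, and the same MNAR mask.

## 8. Numerical choices and problem sizes

* Zero intensities are converted to missing on import (LFQ convention);
  log transforms error on non-positive valid values.
* Cumulative-abundance ties break by protein ID; PCA signs are fixed by
  orienting each component's largest-magnitude loading positive; cluster
  labels are relabeled by first appearance.
* Degenerate zero-variance proteins are flagged, not dropped; complexes
  with < 2 quantified members are "not evaluable", not errors.
* The imputation RNG is a single stream ordered by (sample, protein).
* Validation problem sizes were chosen for single-CPU runs: 2000-protein
  atlases and cohorts, 20 cohort replicates for FDR/sensitivity
  estimates, 1e5 imputation draws for moment checks, exhaustive
  enumeration of Fisher tables up to 12 replicates and random
  backgrounds up to N = 60 for the enrichment oracle. Clustering
  recovery of the planted blocks is evaluated on complete-data atlases
  (CV 20%, no missingness): with the default MNAR mask the imputed
  profiles of low-abundance block members degrade and the adjusted Rand
  index drops to ~0.8, which measures imputation distortion rather than
  clustering correctness; both numbers are reported by the acceptance
  script.

## 9. Known limitations

* The ruler inherits every LFQ bias: ionization efficiency differences
  between proteins propagate directly into copy numbers; estimates are
  order-of-magnitude anatomy, not absolute quantification with spike-ins.
* Molecular weights are taken per protein group (leading protein);
  isoform-resolved MW handling is out of scope.
* ANCOVA assumes homogeneous covariate slopes across groups and Gaussian
  residuals; the diagnostic screen reports, but does not act on,
  violations.
* The uncorrected Fisher marker screen is a candidate generator, not an
  error-controlled discovery procedure; the BH column is provided for
  users who need control.
* The generator's independence and shared-baseline assumptions mean
  passing tests do not certify behavior under correlated proteins,
  batch effects, or normalization failures.
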