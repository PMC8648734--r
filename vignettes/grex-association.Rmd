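---
title: "Genetically regulated expression association: models, design decisions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetically regulated expression association: models, design decisions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grexpipe)
```

# The model

A transcriptome-wide association study replaces the variant with the gene as
the unit of testing. A tissue-specific weight model maps variants (with an
effect allele) to linear weights trained on a reference transcriptome panel;
applied to a cohort's dosages it yields genetically regulated expression,

$$\mathrm{GReX}_{ig} = \sum_l w_{lg}\, d'_{il},$$

the component of expression attributable to germline genotype. Because GReX
is a genotype function, it is free of reverse causation and of the
environmental and temporal noise in measured expression, and it can be
computed in any genotyped cohort — or approximated from GWAS summary
statistics alone.

`grexpipe` covers the downstream chain: imputation, Firth-penalized
single-tissue association, conditional analysis against known risk SNPs,
cross-tissue combination, summary-statistic association, sample-size-weighted
meta-analysis with joint FDR control, and post-hoc evaluation statistics.
Model *training* is out of scope; models arrive as (gene, tissue, variant,
effect allele, weight) tables.

## Why Firth regression

Case-control cohorts are routinely imbalanced, and a GReX column can be
nearly separated in a small study. Ordinary logistic ML is biased in these
regimes and diverges under separation. The Firth fit maximizes the
Jeffreys-prior-penalized likelihood

$$l^*(\beta) = l(\beta) + \tfrac12 \log \det I(\beta),$$

via the bias-corrected score
$U^*_j = \sum_i \{y_i - p_i + h_i(\tfrac12 - p_i)\}x_{ij}$, where $h_i$ are
the leverages of the weighted hat matrix. Estimates are finite for any
dataset with at least one case and one control, and approach ordinary ML as
$n$ grows (the test suite verifies a relative gap below 1% at $n = 10^4$ on
a balanced fixture).

**The penalized likelihood-ratio test.** The default per-term p-value
compares the full fit against the fit with that coefficient *constrained to
zero but with the full design retained inside the penalty*, referring
$2(l^*_{\mathrm{full}} - l^*_{\mathrm{reduced}})$ to $\chi^2_1$. This
constrained-null construction matters: if the reduced model simply dropped
the column, the $\tfrac12\log\det I$ terms of the two models would differ by
a data-independent $O(\log n)$ amount and the statistic would be wildly
anti-conservative — in a null simulation at $n = 2000$ every p-value landed
below 0.015. With the constrained null the same simulation is uniform. A
Wald option ($z = \beta/\mathrm{se}$) is provided; both routes emit a signed
z (for the likelihood route, $z = \mathrm{sign}(\beta)\,|\Phi^{-1}(p/2)|$)
so that meta-analysis always receives direction.

Numerical settings: convergence at max modified score $< 10^{-8}$, at most
50 Newton iterations with up to 5 step-halvings per iteration (each step is
accepted only if the penalized likelihood does not decrease). These match
common Firth implementations and guarantee monotone ascent.

## Conditional analysis and tag SNPs

A significant gene near a known risk SNP may only re-describe that SNP's
signal. Conditioning adds the SNP's dosage (or the GReX of the gene
attributed to the SNP) as a covariate; signal that survives is independent.
When the index SNP is absent from a dataset, `select_tag_snp()` picks the
available variant with maximal squared dosage correlation in a reference
panel, requiring $r^2 > 0.6$, breaking ties toward the variant nearest the
index position and then the lowest position. A conditioning column with
$|r| > 0.999$ against the tested GReX is rejected as collinear rather than
fitted — a nearly-deterministic overlap leaves the likelihood surface flat
and the "independent" signal meaningless.

## Cross-tissue combination

Expression regulation is extensively shared across tissues, so a gene with
modest but consistent signals in many tissues can miss every single-tissue
threshold. Per gene, the available tissue columns are centered, unit-scaled
(correlation-matrix PCA — the scale-free choice, preventing high-variance
tissues from dominating and making the variance rule invariant to units)
and eigendecomposed; the smallest number of leading components whose
cumulative explained variance reaches 0.8 is carried into a Firth LRT with
that many degrees of freedom. Ties at exactly 80% resolve toward fewer
components. Each component is oriented so its largest-magnitude loading is
positive — a reporting convention only; p-values are sign-invariant.
Eligibility defaults to ≥5 tissues (all-tissue scope) and ≥3 (brain scope).
PCA runs per study and the results are meta-analyzed, which keeps studies
independent at the cost of slightly different PC bases per study.

## Summary-statistic association

When only GWAS summary statistics exist, the gene-level z is assembled from
per-variant z-scores and an LD reference:

$$z_g = \sum_l w_l \frac{\sigma_l}{\sigma_g} z_l,
\qquad \sigma_g^2 = \sum_l\sum_m w_l w_m \Gamma_{lm},$$

with $\Gamma$ the dosage covariance of the model variants in the reference
and $\sigma_l^2$ its diagonal. Summary records whose coded allele is the
model entry's other allele are sign-flipped before combination; the
statistic is invariant to allele recoding and to positive rescaling of the
weights (both property-tested). The cross-tissue summary test
eigendecomposes the model-implied tissue correlation
$C = \mathrm{corr}(W'\Gamma W)$, discards components with condition number
above 30 (the truncation convention of the upstream tooling, exposed as an
argument), and refers the quadratic form of the rotated z vector to
$\chi^2$ with df equal to the retained components — the large-reference
limit of an F test, appropriate because synthetic reference panels here are
the cohorts themselves.

The package deliberately keeps the LD reference an explicit input: the same
machinery accepts an in-cohort covariance or an external panel, which is
what makes the internal-vs-external sensitivity comparison possible.

## Meta-analysis and multiple testing

Per-study signed z-scores are combined as
$Z = \sum_i \sqrt{N_i}\, z_i / \sqrt{\sum_i N_i}$ — the sample-size
weighting of METAL, standard normal under the null. An N-proportional
variant circulates in print, but published per-study TWAS rows recombine
correctly only under the $\sqrt{N}$ form, so that is the default and the
alternative sits behind `weighting = "n"` (the README shows the discrepancy
numerically). Two-sided p-values throughout;
duplicate study rows are *not* collapsed — feeding the same study twice
changes the result, by design, since de-duplication is a data-management
concern.

FDR control pools every test — all tissues, both cross-tissue scopes, all
genes — into one Benjamini–Hochberg family at q = 0.05, matching study-wide
correction; per-tissue families are available by subsetting before
adjustment. Novelty annotation flags a gene as "known-region" when its
transcription start lies within 10 Mb of any known risk SNP on the same
chromosome (chromosome labels normalized, `chr1` ≡ `1`); the boundary is
inclusive at exactly 10 Mb.

## Evaluation statistics

* **Storey π₁** — $\hat\pi_0(\lambda) = \#\{p > \lambda\}/\{m(1-\lambda)\}$
  over $\lambda \in \{0.05, \dots, 0.95\}$; the default smoother fits a
  cubic smoothing spline (df = 3) and reads off the value at the largest
  $\lambda$; a fixed-$\lambda = 0.5$ mode exists for tiny sets. The grid and
  smoother settings are the cited method's defaults, flagged here as
  assumptions since no exact settings are published for the application.
* **Median-based MR** — per-instrument Wald ratios
  $r_l = \beta^{out}_l/\beta^{exp}_l$; simple or inverse-variance-weighted
  median (weights $(\beta^{exp}_l/se^{out}_l)^2$, the first-order ratio
  precision); SE by parametric bootstrap resampling effect estimates from
  their stated normals, seed mandatory. The median tolerates up to half the
  instruments being pleiotropic. Both weightings are provided because the
  application does not record which produced its counts.
* **Enrichment ratio** — proportion of heritability over proportion of
  SNPs, exact; with an SE of the heritability proportion, a normal
  approximation against enrichment = 1. The LD-score regression that
  produces the proportions is an external tool and is not re-implemented.
* **Concordance** — r² of log-transformed p over shared (gene, tissue)
  keys, plus exclusive/common significant counts under per-method BH.

# The synthetic-data generator

The generator emulates the structural features the pipeline is sensitive
to, with defaults chosen once as a realistic compact design:

* **Haplotypes**: Gaussian copula, AR(1) with correlation `ld_rho` inside
  blocks of `block_size` variants, independence across blocks; each latent
  value is thresholded at the variant's MAF quantile and dosage is the sum
  of two haplotypes. This gives tunable, monotone LD (property-tested over
  rho ∈ {0, 0.3, 0.6, 0.9}) at a fraction of the cost of coalescent
  simulation. Note the attenuation: thresholding roughly halves the
  dosage-scale $r^2$ relative to the latent correlation (latent 0.95 with
  equal MAFs ≈ dosage $r^2$ 0.62), which matters when choosing `ld_rho` for
  tag-SNP regimes.
* **Imputation quality** is Uniform(0.3, 1) per variant, so the standard
  R² > 0.5 filter has real effect even though simulated dosages are exact.
* **Weight models**: per gene, a window of `snps_per_gene` consecutive
  variants; nonzero weights are Bernoulli(`weight_sparsity`) draws from a
  normal, rescaled so predicted expression has ≈unit variance under
  Hardy-Weinberg (ignoring LD) — making liability effects comparable across
  genes. A causal-tissue weight is copied into another tissue with
  probability `cross_tissue_sharing`, scaled by a per-tissue factor
  (N(1, `tissue_factor_sd`), drawn once per tissue and possibly negative);
  SNPs without a causal-tissue weight may gain a tissue-private one with
  the residual probability.
* **Phenotype**: liability = intercept + Σ β_g · GReX(causal tissue) +
  γ_sex·sex + γ_age·age′; the intercept is found by bisection so the
  expected case fraction hits the target within 1e-6. Age is N(75, 8)
  truncated to [60, 95] — a late-onset design — shared by cases and
  controls; sex is Bernoulli(0.5); genetic PCs are standard-normal null
  covariates. The effect-size scale `effect_sd` is a free parameter of the
  simulator, not an estimate of any real trait's architecture.
* **GWAS summary statistics** use ordinary (non-Firth) logistic Wald tests
  with the same covariate adjustment — matching the practice that produces
  published summary statistics — and the LD reference is the empirical
  model-variant covariance in the same cohort.
* **Determinism**: all draws flow from one seed through a documented
  splitting scheme (`derive_seed`), so module-level reruns reproduce
  bit-identically and every downstream test can score against the stored
  truth record without re-simulation.

What the generator does **not** emulate: real human LD (block lengths,
allele-frequency-dependent LD decay), population structure and admixture,
relatedness, the X chromosome, genotyping error, or tissue-specific eQTL
architectures estimated from data. Passing tests therefore demonstrate
correctness and calibration of the machinery under a controlled generative
model, not performance on real cohorts.

# Validation studies shipped with the package

The `benchmark_*` functions are fixed, seed-driven simulation studies used
by the test suite and the reproduction script; sizes were chosen to give
stable Monte-Carlo estimates on a single core in minutes.

* **Null calibration** (`benchmark_null_calibration`): cohorts of n = 1000
  with 20% cases — the imbalance regime that motivates the Firth penalty —
  and no causal gene; 3 replicate cohorts of 200 genes × 5 tissues for the
  single-tissue test (~2800 null tests) and 12 cohorts for the cross-tissue
  LRT (~2200 eligible null genes). Both tests are required to hold
  empirical type-I error within [0.03, 0.07] at nominal 0.05.
* **Recovery and conditional suppression** (`benchmark_recovery`): two
  studies of 2500 (20% cases), one causal gene at liability β = 0.4. The
  causal gene's model is a *designed* two-eQTL architecture — a dominant
  lead eQTL and a minor secondary eQTL on the adjacent variant of the same
  high-LD block (weight ratio 10:1, predicted-expression SD ≈ 0.5). The
  design mirrors loci where a known risk SNP carries nearly all of a gene's
  regulatory signal, which is exactly the case conditional analysis exists
  to expose: the gene should dominate the meta-analysis unconditionally
  (expected |z| ≈ 5.7) and lose significance once its lead eQTL is adjusted
  for, while staying below the collinearity guard (residual variance share
  ≈ 0.5–1%, so |r| ≈ 0.997 < 0.999). A fully single-eQTL model would make
  GReX and the conditioning dosage exactly collinear and is rejected by the
  guard rather than tested.
* **Concordance** (`benchmark_concordance`): one study of n = 2000 with
  eight modest causal genes; the Firth route against the summary route on
  the cohort's own GWAS, with the in-cohort LD reference and with a
  reference from an independent cohort of the same design. In-cohort
  concordance of log p is expected above r² = 0.9; swapping in the external
  reference strictly lowers it. At this scale both r² values sit near 1 —
  far above what real consortium data show — because the external panel
  shares the exact generative LD process; the direction of the degradation,
  not its magnitude, is the transferable observation.
* **π₁ recovery** (`benchmark_pi1`): ten mixtures of 10⁴ tests with 30%
  alternatives (z shifted by 3); the mean estimate is required within
  ±0.05 of 0.3.

# Degenerate inputs and edge policies

Monomorphic variants get z = 0 with a flag and are excluded from LD
covariances. Constant GReX columns are untestable and dropped with a
warning. Models with zero usable variants after harmonization are omitted
(warning), and coverage (n used / n in model) is always reported so users
can filter low-coverage genes. Strand-ambiguous variants are matched by
exact allele pair — synthetic data share one strand convention; real-data
use should drop them. GReX values enter tests raw (upstream convention; the
choice is inert to the likelihood-ratio p-value up to column scaling).
Variant identity prefers (chromosome, position, allele pair) with rsid as a
fallback key. An LRT with zero retained components is rejected as invalid
input rather than reported as L = 0.

# Known limitations

Individual-level and summary-level routes assume unrelated samples of a
single, PC-adjustable ancestry; no mixed models. Weight-model training,
fine-mapping (posterior inclusion probabilities), z-score imputation for
missing summary statistics, and LD-score regression are out of scope. The
relational single-file weight-database format is supported through an
equivalent flat TSV schema (`write_weights_tsv()` / `read_weights_tsv()`);
the pipeline is format-thin by design. Heterogeneity-aware (random-effects)
meta-analysis is not provided; the weighted-z scheme assumes a shared
effect direction across studies.
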