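---
title: "Decomposing genetic variance in open-pollinated family tests with marker-based kernels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing genetic variance in open-pollinated family tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opgblup)
```

## The problem

Open-pollinated (OP) progeny testing evaluates candidate mother trees through
their wind-pollinated offspring. The offspring of one dam are conventionally
treated as independent maternal half-sib families, which fixes every
within-family additive relationship at 0.25 in the pedigree numerator
relationship matrix **A**. Real OP families violate this assumption: pollen
clouds are finite, so some sibs share a father (full-sibs, relationship 0.5),
and some offspring are selfs of the dam (relationship 1 and inbred). Because
the pedigree model prices all within-family resemblance at 0.25, any excess
resemblance created by this hidden relatedness is booked as additive genetic
variance, inflating heritability and breeding values. A shallow OP pedigree
also cannot separate additive from dominance or epistatic variance at all.

Dense SNP genotypes replace the *expected* relationships of **A** with
*realized* relationships: the observed fraction of shared alleles, which
differs among sibs (Mendelian sampling) and detects hidden full-sibs, selfs
and cryptic among-family relatedness. With marker-based kernels for distinct
genetic effect classes, one random term per class, the genetic variance can
be decomposed even under a shallow OP structure.

## Kernels

With `M` the dosage matrix (0/1/2 copies of the counted allele) and `p` the
per-locus allele frequencies:

* **Additive (VanRaden):** `G_add = ZZ' / (2 * sum p_i(1-p_i))`, where
  `Z = M - 2p` centers each locus.
* **Dominance (Vitezica coding):** `G_dom = WW' / sum (2 p_i q_i)^2`, where
  the locus code is `-2p^2` / `2pq` / `-2q^2` for the reference homozygote /
  heterozygote / alternative homozygote. The printed denominator is read as
  the sum over loci of `(2 p_i q_i)^2`; both codings are zero-mean under
  Hardy-Weinberg proportions. A `genotypic` alternative (Su coding: the
  heterozygosity indicator centered by `2pq`, denominator
  `sum 2 p_i q_i (1 - 2 p_i q_i)`) is also available; the two coincide at
  `p = 0.5` and generally differ in scale.
* **Epistasis:** first-order interaction kernels are Hadamard (entrywise)
  products: `AxA = G_add # G_add`, `DxD = G_dom # G_dom`,
  `AxD = G_add # G_dom`. The Schur product theorem keeps them PSD.
* **Pedigree:** `A` by the tabular method; exact rational relationships to
  machine precision (half-sibs 0.25, parent-offspring 0.5, selfs add the
  inbreeding term).

Missing dosages are mean-imputed with `2p` before centering (the zero-mean
code for the dominance kernels), which preserves the zero-centering of every
column; whether the motivating study imputed or excluded missing genotypes is
not stated, so both the observed-sample and externally supplied (e.g.
founder) frequency conventions are exposed — the default is the observed
sample, and every simulation-based check in this package supplies the true
founder frequencies.

Monomorphic loci are dropped before kernel construction (their denominators
vanish). `stabilize()` blends a kernel with the identity,
`K* = (1-eps) K + eps I` (default `eps = 0.01`), and is only needed when a
fit reports a non-positive-definite covariance; `A` from the tabular method
is PD by construction.

## The model ladder

All models share the fixed overall mean and random replication and
replication-by-family terms (identity covariance over their levels), plus:

| model | genetic random terms |
|---|---|
| ABLUP | additive with **A** |
| GBLUP-A | additive with `G_add` |
| GBLUP-AD | + dominance with `G_dom` |
| GBLUP-ADE | + `AxA`, `DxD`, `AxD` |
| GBLUP-AE | additive + `AxA` only |

Narrow-sense heritability is `h2 = s2_a / (s2_a + s2_d + s2_aa + s2_dd +
s2_ad + s2_e)` over the genetic terms present — the design variances
(replication, rep-by-family) are excluded from the denominator, a convention
chosen for consistency with how published OP heritabilities back-calculate
from their printed components; the percent-of-total decomposition
(`variance_proportions()`) *includes* them, so both conventions are exposed
as separate operations. The `h2` SE uses the delta method on the asymptotic
covariance of the variance-component estimates. `AIC = -2 logL + 2t` with
`t` the number of variance parameters; the REML likelihood omits
software-specific constants, so AIC values are comparable only within this
implementation. The eigen-diagnostic `F = L^{-1/2} V L^{-1/2}` rescales the
asymptotic covariance `V` of the variance estimates to a sampling
correlation matrix; the closer the cumulative eigenvalue curve is to the
straight diagonal, the closer the estimates are to orthogonal.

## REML algorithm and numerical choices

Average-information REML on `V(theta) = sum_t theta_t Z_t K_t Z_t' +
theta_e I`:

* three initial EM iterations for stability, then AI steps;
* traces use the identity `tr(V^{-1} K) = sum(V^{-1} * K)` for symmetric
  `K`, so each iteration costs one Cholesky plus `O(t n^2)`;
* a Levenberg–Marquardt ladder (damping 0, 1e-6, ..., 1e2 on the AI matrix)
  with one step-halving per level, falling back to a monotone EM step if no
  damped step improves the likelihood — this matters when kernels are
  strongly collinear (`cor(G_add, AxA)` is typically > 0.9 on OP data, the
  "tug-of-war" between additive and additive-by-additive variance);
* components are bounded below at `1e-6 * var(y)`; parameters pinned at the
  bound with an outward gradient leave the active set, are excluded from the
  convergence test, and are reported with `SE = NA` (not estimable);
* convergence requires `|dlogL| < 1e-6` *and* maximum relative parameter
  change `< 1e-6`, within 200 iterations; starting values split the
  phenotypic variance equally.

BLUPs come from `u_t = theta_t K_t[ , obs] P y` at the converged estimates,
so individuals present in a kernel but without phenotypes are predicted
through the covariance structure. The SEP of each effect is the square root
of its prediction-error variance `theta_t K_t - theta_t^2 K_t[, obs] P
K_t[obs, ]`; for phenotyped individuals it can never exceed the prior SD
`sqrt(theta_t K_ii)`.

Degenerate inputs: a constant response drives all non-residual components to
the lower bound; an exactly confounded pair of terms (e.g. rep-by-family
with all singleton cells versus the residual) converges to a likelihood
ridge where the ambiguous direction simply stops moving and both SEs are
flagged non-estimable.

## Cross-validation

`make_folds()` builds 10-fold, 5-replicate plans: `random` (near-equal
folds), `family` (whole families per fold, removing all pedigree links
between training and validation) and `block` (each block in turn is the
validation set). In every scheme the validation individuals keep their rows
and columns in the genomic kernels but lose their phenotypes during the
training fit, which is exactly what lets markers predict *across* families
while the pedigree model cannot: under family folding `A[val, train] = 0`,
the validation BLUP deviations are exactly zero, and the accuracy is
undefined (reported `NA`, not 0).

Accuracy is the Pearson correlation between full-data EBVs of model *l* and
cross-validated PBVs of model *m*, computed per replication and averaged,
with `SEM = sd(r)/sqrt(reps)`.

Two design choices were genuinely open:

* *Per-fold re-estimation.* Variance components are re-used from the
  full-data fit by default (`reestimate = TRUE` re-runs REML per fold).
  Re-use is standard practice in genomic-selection cross-validation, is an
  order of magnitude faster, and makes the degenerate one-fold identity
  (PBV = EBV) exact.
* *Block folding.* The description "the remaining five blocks were randomly
  divided into 10 folds as the training population" does not pin down how
  ten training folds combine with one validation block. The default trains
  `k` models per validation block (each omitting one training fold) and
  averages the predictions per individual; `block_mode = "loo"` trains one
  model on all remaining blocks. Both are exposed because the difference is
  within replication noise on simulated data.

## The synthetic generator

`sim_config()` defaults emulate the motivating trial: 214 OP families, 8
offspring each, six blocks with families spread round-robin (about 1.3
trees per family per block), a dense biallelic panel with founder MAF drawn
uniformly from [0.05, 0.5] (a realistic ascertainment window for an SNP
array), and height-scale variance targets taken from the full-decomposition
fit of the motivating study. Contamination defaults are selfing 0.05 and
repeated-sire 0.10 — the true rates in the source population are unknown,
so these are explicit, configurable placeholders.

Mechanics worth knowing when interpreting tests:

* Founders are in Hardy-Weinberg equilibrium; gametes segregate
  independently per locus (no linkage). Linkage disequilibrium, selection
  and population structure are deliberately absent, so passing tests say
  nothing about LD-driven inflation or structure confounding in real data.
* Fresh pollen-pool sires are drawn *without replacement* within a family,
  so an uncontaminated family is a strict maternal half-sib group.
* True breeding values are linear in centered dosages; dominance is a
  heterozygote effect on a locus subset; additive-by-additive values are
  products of centered dosages on random locus pairs — the same orthogonal
  decomposition the kernels estimate.
* Genetic effect sizes are *empirically rescaled* so realized variances hit
  their targets exactly; design and residual effects are drawn at their
  nominal variances. This makes parameter-recovery checks sharp: any bias
  seen downstream is the estimator's, not the generator's.

## Problem sizes used in the checks

The test-suite experiments run at sizes chosen to keep the whole suite in a
few minutes while leaving the estimands unambiguous: kernel expectations on
120 families by 8 offspring at 2000 loci; GBLUP-A heritability recovery at
200 families and 3000 loci over 10 seeds (mean within 0.05 of the 0.25
truth); GBLUP-AE recovery of the additive and additive-by-additive
variances at 200 families and 1500 loci over 10 seeds (means within two
empirical SDs of truth — the AxA component is intrinsically noisy because
`AxA` is almost collinear with `G_add`); and the pedigree-inflation
contrast at 120 families with selfing 0.15 and repeated-sire 0.30, where
the contamination signal clearly exceeds the sampling error of the pedigree
additive variance (at 50 families it does not — the contrast is real but
underpowered).

## Known limitations

* Single site, single trait per fit; no genotype-by-environment terms, no
  spatial residuals, no multi-trait REML.
* Dense-matrix algebra throughout: comfortable to a few thousand
  individuals, not designed for hundred-thousand-animal evaluations.
* AIC is implementation-relative (REML constant differs across software).
* The dominance and epistatic components of real OP data are weakly
  identified (few effective full-sib pairs, `AxA` nearly collinear with
  `G_add`); expect boundary estimates and wide SEs — the package reports
  them honestly rather than hiding them.
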