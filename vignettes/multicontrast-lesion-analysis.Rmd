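---
title: "Multicontrast lesion quantification: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multicontrast lesion quantification: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmrilesion)
```

## The model

Focal demyelinating lesions are heterogeneous: some are dominated by
inflammatory edema, others by demyelination and axonal loss. Quantitative
MRI contrasts separate these processes — T1 and T2 relaxation times rise
with edema and tissue loss, T2\* is sensitive to inflammation and iron, and
MTR falls with myelin/macromolecular loss. This package operationalizes
that reading as a normative z-score model.

For each contrast $c \in \{T1, T2, T2^*, MTR\}$ the healthy-control cohort
defines compartment statistics $\mu_c(L,T)$, $\sigma_c(L,T)$ over lobes
$L$ (frontal, parietal, occipital, temporal, cerebellum) and tissues $T$
(WM, GM). A lesion with voxel set $l$ and $N$ voxels gets

$$z_c \;=\; \frac{1}{N}\sum_{v \in l}
  \frac{I_c(v) - \mu_c(L_v, T_v)}{\sigma_c(L_v, T_v)},$$

the mean voxelwise standardized residual. Each $z_c$ is discretized at
$\pm 2$ into LOW / NORMAL / HIGH (a standard normal puts more than 95% of
its mass in $[-2, 2]$, so values beyond it mark changes significant at
roughly the 5% level), and the joint tri-state pattern — the lesion's
*combination signature*, one of $3^4 = 81$ — is mapped to pathology groups:

* **Group 1** — all four NORMAL: no significant change;
* **Group 2** — T1 and MTR NORMAL, T2 and/or T2\* HIGH (none LOW):
  prevalent inflammatory edema;
* **Group 3** — T1 HIGH, MTR NORMAL, T2/T2\* NORMAL or HIGH:
  microdegeneration with or without inflammation;
* **Group 4** — T1 HIGH, MTR LOW, T2/T2\* NORMAL or HIGH:
  prevalent tissue loss;
* **OTHER** — everything else (any T1/T2/T2\* decrease, MTR increase, …),
  patterns not part of the four-group taxonomy.

The rules are mutually exclusive and exhaustive over all 81 signatures;
`tests/testthat/test-acceptance.R` verifies the partition by brute-force
enumeration against independently evaluated predicates.

Per-subject lesion load enters the clinical stage as the mean lesion volume
(MLV) of each observed combination: total TIV-normalized lesion volume
divided by lesion count, zero when a subject lacks that combination. Each
clinical score is then modelled by ordinary least squares after backward
stepwise selection over MLV columns plus covariates, with Box-Cox
normalization, Bonferroni correction over the model family, and
leave-one-out (LOO) cross-validation.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| z threshold | 2 | dimensionless | > 95% of N(0,1) inside the closed interval $[-2,2]$ |
| lesion size filter | > 10 | voxels | strict inequality; guards tiny components against low-resolution T2 sampling noise |
| connectivity | 26 | — | common volumetric default; 6/18 configurable |
| Bonferroni m | 7 | tests | one per modelled clinical score |
| stepwise criterion | AIC | — | reproducible common default; `criterion = "pvalue"`, `alpha = 0.05` brackets the plausible alternative |
| Box-Cox λ grid | $[-3, 3]$ step 0.01 | — | bounded ML search; λ fixed at grid resolution |
| Box-Cox scope | all scores except MSFC | — | composite MSFC left on its native scale; configurable |
| reference pooling | voxel | — | `pooling = "subject"` averages per-subject statistics instead |
| z compartment mode | per-voxel | — | `compartment = "majority"` reproduces a strict per-lesion reading |

## Design decisions where the design was open

**Pooled versus per-subject reference statistics.** A single $\mu, \sigma$
per compartment is required, but whether HC voxels are pooled across
subjects or per-subject statistics are averaged is underdetermined. The
default pools voxels (each voxel is one draw from the compartment
distribution, and the pooled SD absorbs between-subject variance, which is
what a z-score against "the HC distribution" should include); the
subject-level alternative is a switch.

**Mixed-tissue lesions.** Writing the reference as a single
$(\mu(L_l,T_l), \sigma(L_l,T_l))$ per lesion is ill-defined for cortical
type I lesions spanning GM and WM. The default standardizes every voxel by
its own compartment inside the sum — well-defined for every lesion and
identical to the per-lesion form when the lesion is homogeneous. The
majority-compartment mode is kept as an option for strict comparability.

**Boundary and tie rules.** $z = \pm 2$ exactly is NORMAL (closed
reference interval). Lobe assignment is the majority lobe with ties broken
by the fixed lobe order; the tri-state letters sort LOW < NORMAL < HIGH
and combination rows sort by group then lexicographically, so table layouts
are deterministic. Display ordinals (`combination` 1..n) are derived from
that order; signatures themselves are the primary keys, since a printed
1–12 numbering cannot be reconstructed unambiguously from group
descriptions alone.

**Background voxels.** Mask/atlas edge effects can put lesion voxels on
background labels, where the z-score is undefined. Such voxels are excluded
from the sum; a lesion more than 50% on background is dropped.

**Intercept-only LOO.** If selection retains no predictors, the LOO
prediction for subject $i$ is $(\sum_j y_j - y_i)/(n-1)$ — an exact affine
function of $y_i$ — and a predicted-versus-observed fit would be spuriously
perfect. The LOO summary is reported as NA in that case.

**Stepwise with p ≥ n.** With more candidate combinations than subjects the
full starting model is singular; candidates are pre-screened to the
$\lfloor n/2 \rfloor$ predictors with the largest absolute marginal
correlation before elimination starts, and zero-variance (never-observed)
predictors are dropped and logged.

## What the synthetic generator emulates — and what it does not

The phantom states the world the tests assume. Healthy tissue is Gaussian
per (lobe, tissue, contrast), with 3 T-typical means (e.g. WM T1 ≈ 850 ms,
GM T1 ≈ 1400 ms, WM MTR ≈ 0.45) and small deterministic lobe offsets.
Lesions are connected quasi-spherical blobs grown best-first inside
compatible tissue, non-adjacent by construction so union components remain
distinct; within a lesion each contrast is redrawn with its mean shifted by
the configured effect in units of the local SD. The four group patterns use
|effect| = 4 SD on their non-null contrasts — the group taxonomy fixes
effect *directions* only, and 4 SD is the package's choice of a clearly
super-threshold lesion (threshold 2 plus sampling noise $1/\sqrt{N}$),
documented here and not tuned thereafter. Default cohort sizes (18 HC, 36
patients) mirror a typical single-center study; lesion sizes are drawn
uniformly from 15–40 voxels. Three pseudo-contrast masks per lesion
exercise union merging; `mask_fraction < 1` emulates differing lesion
conspicuity by taking random connected subsets (≥ 60%).

Clinical scores come from a known linear model on MLV predictors and
covariates with Gaussian noise; the default gives three true predictors a
standardized effect of ≈ 0.4 residual SDs per predictor SD — strong enough
that backward elimination should find them at n ≈ 150, weak enough that
selection is not trivial.

Deliberately absent: MR physics (partial-volume effects, bias fields,
noise correlations), registration error, anatomically shaped atlases,
lesion mass effects, and any relation between lesion location and symptom
domain. A green recovery test therefore establishes that the pipeline's
*statistical logic* is correct under its own assumptions — not that the
taxonomy is biologically valid, and not performance on real scanner data.
Likewise, fitted clinical models from real cohorts (their coefficients and
adjusted R² values) cannot be reproduced without the underlying subject
data; the regression stage is validated by parameter recovery on synthetic
data instead.

## Numerical notes

* Compartment SDs use the $n-1$ denominator; a zero-variance compartment
  raises a degenerate-reference error rather than returning infinite z.
* Connected components and region growing are deterministic (BFS in
  column-major order; candidates ranked by Euclidean distance to the seed).
* One global seed expands into per-subject RNG streams by fixed offsets, so
  cohorts are reproducible and subjects independent; all offsets stay below
  $2^{31}$.
* The Box-Cox λ is an ML grid search; agreement with the profile-likelihood
  implementation in MASS is tested to grid resolution.
* AIC comparisons on exact (zero-residual) fits are degenerate; the
  noiseless recovery test asserts the signal predictor's retention and
  coefficient, not uniqueness of the selected set.

## Known limitations

* The NIfTI-1 reader/writer is minimal (uncompressed single-file `.nii`,
  five datatypes, no orientation handling beyond voxel size); inputs are
  assumed co-registered and identically gridded.
* T2 maps acquired at lower resolution must be resampled upstream; the
  package treats all maps as voxel-aligned.
* No covariate-adjusted (age/sex-conditional) normative model; the
  reference is a single HC pool.
* Stepwise selection inherits the usual instability of subset selection;
  the null-retention rate of the AIC criterion is monitored by test, not
  suppressed.
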