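---
title: "Generating and validating virtual patient populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating and validating virtual patient populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vpop)
```

## The problem

A real clinical cohort of a few hundred coronary-artery-disease patients is
too small for in-silico trials, which may need tens of thousands of
patients. `vpop` fits a joint statistical model to the real cohort and
samples from it, so that virtual patients preserve both the marginal
distributions and the interrelationships of the real covariates —
combinations of values that never co-occur in reality should get
(near-)zero probability, which rules out generating each covariate
independently.

## The joint log-normal model

All covariates are treated as jointly log-normal. Clinical quantities
(ages, lipid concentrations, pressures, body-mass index) are positive and
right-skewed, so the multivariate normal is fitted to their natural
logarithms and samples are exponentiated back. This construction guarantees
positivity *by design*: the alternative — sampling a plain multivariate
normal and discarding patients with negative values — distorts the joint
distribution and is deliberately not implemented.

Fitting (`vp_fit`) computes, on the log scale, the mean vector
$\mu$ and covariance matrix $\Sigma$ (with $1/(n-1)$ normalization), then
the eigendecomposition $\Sigma = U \Lambda U^\top$ and the sampling matrix
$K = U \Lambda^{1/2}$. Generation (`vp_generate`, or `simulate()` on the
fitted model) draws standard-normal latent vectors $Z$ and forms

$$x' = \exp(\mu + K Z),$$

so the log-space mean and covariance of the virtual population equal the
fitted ones exactly in distribution. Two notes on deliberately open points:

* **Mean normalization.** The conventional sample mean divides by $n$; a
  $1/(n-1)$ variant is exposed as `vp_fit(..., mean_norm = "n-1")` for
  strict reproduction of formulations that normalize the mean that way. The
  default is $1/n$; the covariance always uses $1/(n-1)$.
* **Latent distribution.** One reading of the log-normal pipeline would
  draw log-normal latents inside the sampling equation. That does not
  reproduce $\Sigma$; the standard construction — normal latents in log
  space, exponentiation afterwards — does, and makes every marginal
  log-normal. The latter is implemented.

### Decomposition backends and degenerate covariances

`backend = "eigen"` (default) matches the $U$, $\Lambda$ notation and
handles positive *semi*-definite matrices; `backend = "cholesky"` uses the
pivoted Cholesky factor $L$ instead. Both satisfy $K K^\top = \Sigma$, so
the sampled distributions are identical. Empirical covariances of collinear
covariates can carry tiny negative eigenvalues from floating-point
rounding; eigenvalues below $10^{-12} \cdot \max\Lambda$ are clipped to
zero rather than raising an error. A zero-variance covariate simply
generates its constant value.

## Categorical covariates

Categorical variables are coded as consecutive integers $1..k$ — starting
at 1, not 0, because the codes pass through the same log pipeline as the
continuous covariates and $\log 0$ is undefined. Simulated values come back
continuous and are matched to codes at *critical values* (CrV). The default
rule, applied after back-transforming to the original scale where code
spacing is again linear, is the midpoint of sequential integers: any value
in $[0.5, 1.5)$ becomes code 1, $[1.5, 2.5)$ becomes 2, and so on. A value
exactly at a boundary goes to the upper code (a measure-zero event needing
only a fixed convention), and codes are clamped to $[1, k]$. The
alternative rule (`build_rule(..., method = "lognormal_quantile")`) places
boundaries at log-normal quantiles
$\mathrm{CrV}(\mu, \sigma, P_i) = e^{\mu + \sigma\,\Phi^{-1}(P_i)}$ with
$P_i$ the cumulative empirical category proportions.

A consequence worth knowing: thresholding a *fitted normal* at code
midpoints attenuates prevalences away from 50%. A binary risk factor
observed at ~65% "Yes" will generate at roughly 55–60%. This is a property
of the method, visible at the same few-percentage-point scale in the
validation tables, not an implementation artifact; the test suite bounds it
at ten percentage points with a median within five on the 186-patient
preset.

## Imputing missing source values

Missing cells in the *real* cohort are filled by inverting the sampling
equation. For a row with known entries $J$, the latent system
$(K Z)_J = (x' - \mu)_J$ is underdetermined; among its infinitely many
solutions the one of least Euclidean norm $\lVert Z \rVert = \sqrt{\sum_j
Z_j^2}$ is selected via the Moore–Penrose pseudoinverse of the known-row
submatrix of $K$ (`solve_latent`). The full row $\mu + K Z$ then supplies
the missing entries; imputed categorical cells are discretized with the
same midpoint rule as generation. Known entries are reproduced to
$10^{-8}$ or better (the per-row `residuals` record this), rows without
missing cells are untouched, and the procedure is idempotent and
deterministic — single imputation, no uncertainty quantification.

Two design choices were genuinely open:

* **Which model to invert when the source itself is incomplete.** The
  moments are estimated from pairwise-complete observations
  (`vp_fit(..., use = "pairwise")`, the minimal-assumption choice), then
  imputation runs once. An optional `iterate = TRUE` mode refits on the
  imputed cohort until the largest cell change drops below `tol` (default
  $10^{-6}$, at most 10 rounds).
* **The norm.** The least-norm criterion is implemented as the Euclidean
  norm — the "length or magnitude" of the latent vector. For a
  multivariate normal, the resulting reconstruction of the missing block
  equals its conditional mean given the observed block, which is why
  imputed values track strongly correlated covariates (the suite verifies
  this against held-out cells and against a brute-force grid search).

## Record linkage

Virtual clinical records (dataset A) carry no geometry; geometry records
(dataset B) carry no clinical covariates. A bridge cohort C carrying both
links them. For each bridge record $c_k$, every A record gets an additive
matching weight — per compared field, an agreement weight if the
comparator says the fields agree (exact match for categorical fields,
$|a-c| \le$ tolerance for numeric ones) and a disagreement weight
otherwise, missing fields contributing zero — and the candidate set
$V_{AC}^k$ keeps those *strictly* above the threshold $\hat W_{AC}$
(ties excluded); likewise $V_{BC}^k$ for B. The virtual population is C
itself (re-keyed, provenance `"bridge"`) plus, per bridge record, all
combinations $V_{AC}^k \times V_{BC}^k$ (provenance `"linked"`), so its
size is $|C| + \sum_k |V_{AC}^k|\,|V_{BC}^k|$.

The weight function and thresholds are configuration, not estimates: the
classical $\log_2(m/u)$ derivation from labeled field statistics is
provided as a helper (`fs_weights`), but defaults are simple $\pm 1$
field weights. The desired "variance" of the linked population is
controlled by lowering thresholds, never by injecting noise into records:
linked records take their clinical fields unchanged from A and their
geometry fields unchanged from B. No blocking or indexing is implemented;
intended population sizes are $\le 10^5$ records.

## Validation metrics

`vp_validate` compares a real and a virtual cohort sharing a schema:

* per variable, the two-sample Kolmogorov–Smirnov statistic
  $\sup_t |\hat F_{real}(t) - \hat F_{virt}(t)|$ ("gof", in $[0,1]$,
  smaller is better; only the statistic is reported, never a p-value).
  For categorical variables it is computed on the integer codes, still a
  valid sup-difference on a discrete support;
* per variable, mean, SD ($1/(n-1)$), skewness $m_3/m_2^{3/2}$ and
  **Pearson kurtosis** $m_4/m_2^2$ (normal $\to$ 3). Kurtosis conventions
  differ across software and are not distinguishable from summary tables
  alone, so the convention is stated in the report header and an
  `excess_kurtosis = TRUE` toggle subtracts 3;
* category percentage tables per cohort (summing to 100%);
* the pairwise Pearson correlation matrices of the log-transformed data,
  summarized by their elementwise maximum absolute difference
  (zero-variance columns yield `NA` and are excluded), plus a legacy block
  with the plain mean/SD of the raw data columns of each cohort.

## The synthetic ground-truth generator

No real cohort ships with the package; `smartool_truth()` defines a fully
known stand-in emulating a 186-patient coronary-artery-disease cohort: 10
continuous covariates (age, BMI, total/LDL/HDL cholesterol, triglycerides,
glucose, creatinine, systolic pressure, CRP) with field-typical means and
coefficients of variation, moment-matched to log-normal parameters; and 10
binary risk factors at prevalences matching a published CAD cohort of that
size (57% male, 15% diabetes, 61% hypertension, ...). Log-space
correlations encode standard clinical structure (total cholesterol–LDL
0.85, BMI–obesity 0.75, glucose–diabetes 0.65, pressure–hypertension 0.55,
current–past smoking −0.45, ...), projected to the nearest positive
semi-definite correlation matrix by eigenvalue clipping. `make_cohort`
samples the latent normal and cuts categorical dimensions at the log-normal
quantiles of their target prevalences; `inject_missing` masks cells
completely at random (MCAR), never leaving a row fully masked and returning
the hidden truth for scoring; `make_geometry_table` emits per-patient
monotone stenosis progressions ending above 50% (the stent-trial population
filter) — an explicit synthetic stand-in for a mechanistic plaque-growth
simulation, not a model of one.

What passing tests on this generator do and do not show: they verify the
*pipeline* — parameter recovery, marginal and correlation reproduction,
imputation accuracy under known structure. Real cohorts add features the
generator omits by design: non-log-normal marginals, informative (non-MCAR)
missingness, measurement error, and categorical variables whose latent
structure is not a thresholded normal. Agreement metrics on real data
should be expected to be somewhat worse than on the synthetic preset.

## Problem sizes and numerical choices, summarized

The test suite and the acceptance script use a 186-patient source, 10,000
virtual patients, and Monte-Carlo checks at $n = 10^4$–$4\cdot 10^4$ with
$5\,\sigma_{max}/\sqrt{n}$ elementwise error bounds; the whole suite runs
in well under a minute on one core. Fixed tolerances: covariance symmetry
$10^{-10}$; eigenvalue clip $10^{-12}\cdot\max\Lambda$; reconstruction
$K K^\top = \Sigma$ to $10^{-8}$; imputation residuals $10^{-8}$;
iteration stop $10^{-6}$. Seeds are plumbed explicitly through every
sampling function and restored afterwards, so library calls never disturb
the caller's RNG stream.

## Known limitations

* Only a Gaussian copula in log space: no mixtures, no non-Gaussian tail
  dependence.
* Single deterministic imputation — no multiple imputation, so downstream
  analyses see no imputation uncertainty.
* Binary prevalence attenuation from midpoint thresholding (quantified
  above).
* No conditional generation (sampling given fixed covariate values) and no
  stratified oversampling.
* Linkage weights and thresholds are user configuration; the package
  supplies machinery and sane defaults, not estimated match probabilities.
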