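---
title: "Methods: probabilistic soil half-life estimation and prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probabilistic soil half-life estimation and prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model behind `dt50prob`, the
defaults and why they were chosen, the numerical machinery, and what the
test suite does and does not establish. It states no empirical result that
the tests or the acceptance script do not themselves compute.

## 1. The estimation problem

A soil biotransformation half-life (DT50) is not a constant of a molecule:
repeating a simulation study in a different soil, with a different
analytical method or kinetic fit, yields a different number, often by
half an order of magnitude or more. Some studies report only a bound
("> last sampling day"). Regulatory classification, however, compares a
single characteristic value against fixed thresholds: persistent (P) at
120 days, very persistent (vP) at 180 days. `dt50prob` resolves this
tension by working with *distributions* end to end and converting them to
class probabilities only at the last step.

## 2. Per-compound Bayesian inference

On the log10-days scale, replicate observations of one compound are
modelled as

$$y_j \mid \mu, \sigma \sim \mathcal N(\mu, \sigma^2), \qquad j = 1 \ldots n,$$

where $\mu$ is the compound's characteristic mean log half-life and
$\sigma$ the between-study variability. A left-censored report ("< c")
contributes $\Phi((c-\mu)/\sigma)$ to the likelihood and a right-censored
report ("> c") contributes $1 - \Phi((c-\mu)/\sigma)$. Priors:

* $\mu \sim \mathcal N(m_0, s_0^2)$ with defaults $m_0 = 1.2$,
  $s_0 = 1.0$ log10 days. Soil half-life collections concentrate around
  1.2 log10 days (about 16 days), and $s_0 = 1$ spans sub-day to
  multi-year half-lives within two prior SDs.
* $\sigma \sim \mathcal N(\sigma_0, \tau_0^2)$ truncated to $\sigma > 0$,
  with defaults $\sigma_0 = 0.3$, $\tau_0 = 0.3$ log10 days: replicate
  scatter of about a factor 2 is typical for soil studies, and the wide
  scale lets the data dominate whenever $n$ is moderate. $\tau_0 = 0$
  degenerates to a fixed, known $\sigma$ (used by the conjugate oracle
  tests). These defaults are configurable stand-ins, not claims about any
  particular data set; they are echoed into every curation output.

The posterior summaries carried forward are `mu_mean` (posterior mean of
$\mu$), `mu_std` (posterior SD of $\mu$ — the *epistemic* uncertainty of
the mean) and `sigma_mean` (posterior mean of $\sigma$ — the *aleatoric*
experimental variability). Modelling `sigma_mean` as a function of
structure is deliberately out of scope.

**Numerics.** Inference is deterministic quadrature on a 400 × 400
$(\mu, \sigma)$ grid spanning $m_0 \pm 6 s_0$ and $(0, \sigma_0 + 6
\tau_0]$ (cell midpoints). There is no sampler, hence no seed sensitivity
and exact order invariance: exact observations enter through their
sufficient statistics $(n, \bar y, SS)$, so cost does not grow with
replicate count; censored observations are added term by term. Uniform
grids are spectrally accurate for Gaussian-like integrands, so the
conjugate closed form is matched to well below $10^{-3}$ whenever the
posterior is resolved by the grid. Two guards:

* if more than 0.1% of posterior mass sits on the outermost cells, the
  grid cannot contain the posterior and inference aborts with a
  resolution error (widen the prior or the spans);
* a posterior narrower than one grid cell reports `mu_std` at the
  cell-resolution floor $\Delta\mu/\sqrt{12}$ rather than 0, preserving
  the `mu_std > 0` invariant for degenerate data (e.g. many identical
  replicates).

Mutually contradictory censored-only data ("> 100" together with "< 1")
still yield a proper posterior because every likelihood factor is positive
for $\sigma > 0$; a warning flags the conflict. Per-compound inference is
fully independent (no partial pooling of $\sigma$ across compounds): the
pooling choice is not forced by anything in the data model, and the
independent version keeps each compound's record self-contained.

## 3. From distributions to REACH classes

For a threshold $T$ in days,

$$p(\log DT_{50} \ge \log T) = 1 - \Phi\!\left(\frac{\log_{10} T - \mu}{s}\right),$$

applied with $T = 120$ (P) and $T = 180$ (vP); $p(nP) = 1 - p(P)$.
Thresholds are inclusive ($\ge$), matching the exceedance formulation, and
configurable for other jurisdictions. Point classification
(`classify_with_ci`) uses either `mu_mean` alone or the conservative upper
95% bound `mu_mean + 1.96 mu_std`. Probabilities are reported both as
floats and as half-up-rounded integer percents, because regulatory tables
print integers and `round()`'s banker's rounding would disagree on .5
cases. Confidence bands on a predictive SD: below 0.5 log10 days "good"
(about 3-fold in days), 0.5–0.7 "acceptable" (about 5-fold), at or above
0.7 "low". The same bands are applied to Bayesian and model-predicted SDs
— the formula is identical and the interpretation (how wide a factor the
half-life may span) carries over.

## 4. Molecular features

Structure handling is delegated to RDKit via a bundled Python helper with
a JSON batch protocol; results are memoised per SMILES. Standardization
canonicalizes and removes all stereochemistry (stereospecific prediction
is out of scope), but keeps isotope labels, so isotopomers remain distinct
records. The applicability domain is: a single connected structure, at
least one carbon, elements within {H, B, C, N, O, F, Si, P, S, Cl, Br, I},
molecular weight under 1200 Da. Multi-fragment inputs (salts, mixtures)
are rejected outright rather than desalted: extracting "the" parent
fragment silently changes the identity of what is being assessed, and a
rejection with reasons is the safer regulatory default.

Feature blocks: MACCS keys (166 bits), Avalon fingerprints (512 bits, the
generator's default length), RDKit path-based fingerprints (2048 bits),
the RDKit 2-D descriptor set, and an `external_table` reader for any
precomputed descriptor CSV (this replaces JVM-based descriptor engines
and database-dependent biotransformation-rule fingerprints while keeping
the pipeline contract). Descriptor columns not computable for every
compound are dropped. Columns are min-max scaled on training compounds
(constant columns to 0; query values outside the training range are *not*
clipped — an out-of-range descriptor is information, not an error), then
filtered at variance 0.02, then de-duplicated: complete-linkage
hierarchical clustering on $1 - |\rho_{Spearman}|$, cut at 0.01
($|\rho| \ge 0.99$), keeping per cluster the member with the highest
variance (ties: first column). Complete linkage is the conservative
choice — a cluster is only formed when *all* members are mutually
redundant — though at a 0.01 cut the linkage choice is nearly immaterial;
it is fixed for reproducibility.

Chemical distance for calibration uses Morgan fingerprints (radius 2,
2048 bits — length matched to the path fingerprint, as no other length is
dictated): distance = 1 − mean Tanimoto similarity to the 5 nearest
training compounds. Two all-zero fingerprints get similarity 0
(conservative, avoids 0/0).

## 5. Probabilistic regressors

**GP regression.** Training covariance
$C = s^2\,g(r/\ell) + \nu I + \mathrm{diag}(\alpha)$, with $g$ the base
kernel (Matérn 2.5 default; Matérn 1.5 and RBF selectable — the kernel is
a configuration choice, not a fixed truth), $s^2$ a constant prefactor,
$\ell$ an isotropic length-scale, $\nu$ a *fitted* white-noise variance,
and $\alpha_i = \mu_{std,i}^2$ the *fixed* per-compound target variances
from curation. $\alpha$ encodes known data uncertainty; $\nu$ absorbs
residual model error on top of it — fitting $\nu$ on top of $\alpha$ keeps
the two roles separate. Targets are centered by the training mean only
(no rescaling), so predictions stay in log10-day units. Hyperparameters
$(s^2, \ell, \nu)$ maximize the log marginal likelihood with analytic
gradients (L-BFGS-B on log parameters, 5 seeded restarts by default,
data-driven initialization at the target variance and median pairwise
distance). Cholesky factorization with jitter escalation ($10^{-8}$
upward, 8 steps) guards positive definiteness. The predictive variance is
$s^2 + \nu - k_*^\top C^{-1} k_*$: it includes the fitted noise floor
(a new measurement of a training compound is still noisy) but not
$\alpha$ (which belongs to the training targets, not the query), and it
never exceeds the prior variance $s^2 + \nu$.

**Random forest baseline.** A compact seeded regression forest (Rcpp):
bootstrap resampling, per-node `mtry` feature subsampling (default
$\lceil p/3 \rceil$), exhaustive variance-reduction splits, 500 trees,
unlimited depth, minimum node size 5. Prediction = tree mean; uncertainty
= population SD across trees, floored at $10^{-3}$ so a single-tree
forest still satisfies `pred_std > 0`. The spread is an empirical proxy —
unlike the GP it is not guaranteed Gaussian, which is the main reason the
GP is the primary model for probability calculations. The RF uses its own
portable xorshift RNG so that identical seeds give bit-identical forests
across platforms and R sessions.

## 6. Evaluation and calibration

Nested cross-validation partitions *compounds* (never observations);
fold assignment is a deterministic function of the id set and the seed,
invariant to input order. Inner folds select a candidate (feature set ×
kernel) by mean inner RMSE — RMSE because it is the headline accuracy
metric; with a single candidate the inner loop is skipped. Scaling and
feature selection are refit inside every training partition, so no test
statistics leak into the pipeline; a dedicated test permutes test-fold
targets and asserts bit-identical fold models. Candidates failing on a
fold are recorded as failures, not propagated.

Calibration metrics:

* **ECE**: over nominal central-coverage levels 0.05, 0.10, …, 0.95 (19
  levels; the grid is a package choice, configurable and reported), mean
  absolute gap between empirical and nominal coverage. Anchors: a
  perfectly calibrated forecaster scores near 0; a zero-residual
  forecaster with positive SD scores exactly `mean(1 - p) = 0.5` on this
  grid.
* **ENCE**: 10 equal-count bins by predicted SD (bin count a package
  default), per bin `|RMV - RMSE| / RMV` with `RMV = sqrt(mean(sd^2))`,
  averaged. Anchors: residuals equal to ±SD give 0; residuals exactly 2×SD
  give 1.
* **Distance calibration**: Pearson and Spearman correlation of predicted
  SD with the Tanimoto 5-NN distance (distance = 1 − similarity; the sign
  convention makes a *positive* correlation the desirable outcome).
  Constant distances or SDs make the correlation undefined; this is
  returned as a flagged `NA`, never silently as 0.

ECE/ENCE are reported pooled over outer-test predictions (headline) and
per fold (breakdown), since either pooling convention is defensible.

## 7. The synthetic world

The generator exists so every module is testable offline. It emulates the
*statistical shape* of a soil-study export: per-compound replicate counts
uniform on 1–59 (the range seen in curated soil packages), observations
log10-normal around a compound mean, replicate SD $\sigma^* \sim
U(0.15, 0.6)$ log10 days (bracketing the typical factor-2 scatter), 5% of
observations converted to right-censored bounds at their own value (the
dominant regulatory case "beyond the last time point"; left-censoring
behind a flag), and compound means affine in five standardized 2-D
descriptors (MolWt, MolLogP, TPSA, rotatable bonds, ring count; weights
0.30/0.35/0.25/0.20/0.15) around an intercept of 1.2 log10 days plus
Normal(0, `noise_sd`) compound noise. The signal weights give a
structural signal SD of roughly 0.6 log10 days against the default
`noise_sd = 0.3`, i.e. a learnable but noisy problem of realistic
hardness. Structures come from a combinatorial vocabulary of
disubstituted benzene/pyridine/thiophene/furan/cyclohexane scaffolds
(about 2700 distinct canonical, AD-passing SMILES). Ground truth is
emitted separately and never consumed by the pipeline.

What the synthetic world does **not** emulate: real pesticide chemistry
and its class structure, correlated replicate designs, soil covariates,
reporting biases, or heavy tails in experimental scatter. A green
end-to-end test therefore establishes that the machinery is correct and
that signal of the stated size is recovered — not that any particular
real-data performance number would be reproduced.

## 8. Scaling choices in the shipped tests

The acceptance-style tests run the sizes their criteria state (e.g. the
end-to-end nested CV at 500 compounds for three noise levels, calibration
anchors at 5000 points, coverage at 200 simulated compounds). Two
supporting tests are deliberately smaller to keep the default suite fast:
the ridge-oracle comparison runs at 200 compounds with 3 outer folds, and
the contraction property uses 50 simulations per replicate-count level;
both are property checks whose conclusions do not depend on the larger
sizes.

## 9. Known limitations

* The Bayesian defaults are stand-ins with a documented rationale; for a
  specific data collection the priors should be reviewed (and can be set
  per run). `mu_std` for single-observation compounds is prior-dominated
  by construction.
* The GP is exact (dense Cholesky); it is comfortable to a few thousand
  training compounds but not beyond.
* The RF spread is not a calibrated Gaussian SD; its persistence
  probabilities should be read as heuristics.
* Multi-fragment inputs are rejected, not desalted; users who want
  parent-fragment scoring must desalt upstream, explicitly.
* The feature pipeline offers no 3-D descriptors (no conformers) and no
  PCA variant (dimensionality reduction added nothing at these feature
  counts and obscures feature provenance).
* Predictions for structures far from the training domain revert to the
  training mean with near-prior uncertainty; the confidence category and
  the distance diagnostic are there to make that visible.
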