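---
title: "Methods: simulation, QC-RLSC and consensus selection in metabodrift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, QC-RLSC and consensus selection in metabodrift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`metabodrift` implements the computational chain of a pooled-QC multi-batch
metabolomics study: a calibrated simulator, QC-based robust LOESS signal
correction (QC-RLSC), batch integration, quality filters, the downstream
statistics, bootstrap Borda consensus feature selection, and an empirical
sample-size study. This vignette explains the models, the tunable
parameters, the numerical choices, and what the package's tests do and do
not demonstrate.

## The generative model

Peak areas are strictly positive and right-skewed, so everything
multiplicative is modelled on the log scale. For feature $j$ at injection
position $p$ of run $r$ in batch $b$:

* **subject injection**: $\;y = B_{ij}\, s_{bj}\, d_{rj}(p)\, \varepsilon$
* **pooled-QC injection**: $\;y = Q_j\, s_{bj}\, d_{rj}(p)\, \varepsilon$

with

* $B_{ij}$ the drift-free biological abundance of subject $i$:
  log-normal around the feature baseline with between-subject log-SD
  $\sigma_b$ (default **0.7**, i.e. inter-subject RSDs around 80 %,
  consistent with the wide biological variation seen for serum metabolite
  features — many well above 100 %, aromatic amino acids much lower);
* $Q_j$ one fixed pooled composition shared by every QC injection — a QC's
  only between-injection variance is technical, which is the property that
  makes it usable for calibration;
* $s_{bj}$ a per-batch multiplicative sensitivity step, log-normal with
  log-SD 0.25 by default (batches acquired months apart);
* $d_{rj}(p) = e^{-\lambda (p-1)}\,[1 + a \sin(2\pi (p-1)/P)]$ a smooth,
  strictly positive attenuation, re-drawn per feature and run:
  total end-of-run attenuation uniform on 20–40 %, sinusoid amplitude
  5–15 % with period 30–60 injections. No functional form for instrument
  drift is canonical; exponential decay modulated by a slow oscillation is
  smooth, positive, and reproduces the "nonlinear attenuation" shape of
  real runs while remaining analytically checkable in tests;
* $\varepsilon$ log-normal technical noise, CV 5 % by default.

Covariate effects ([`effect_spec()`]) shift the log-abundance of the
non-reference group(s) by `effect_size` $\times\,\sigma_b$, so effect sizes
are expressed in biological-SD units. Missingness combines MNAR
left-censoring below a per-feature detection quantile (default 2 %) with a
small MCAR component (1 %) — the detection-limit dropout typical of peak
tables.

The simulator emits a `ground_truth` object holding the drift-free
abundances, the applied drift/step/noise factors, and the missingness
mask; multiplying them back reproduces the raw study bit-for-bit, which is
asserted in the test suite.

### Cohort model

Cohort covariates are drawn from independent log-normal marginals
calibrated to the published median/IQR of a 1,200-subject UK adult serum
study (age 48.0, IQR 40–60, truncated to 19–81 years; BMI 25.63 kg/m²;
SBP 125 / DBP 76 mmHg; male fraction 701/1191; smoking 502:163:176; a
5-assay clinical panel). Design notes:

* a log-normal matches the reported median/IQR asymmetry of every
  continuous marginal to within a few percent; $\sigma$ is the average of
  the upper and lower log-IQR half-widths and the location is solved
  numerically so the *truncated* distribution's median equals the target
  exactly;
* marginals are sampled by Latin-hypercube (stratified-quantile)
  inverse-CDF draws: each covariate fills the $n$ equal-probability strata
  in random order with within-stratum jitter. Draws remain random and
  independent across covariates, but sample quantiles track the
  calibration with $O(1/n)$ rather than $O(1/\sqrt n)$ error — the
  generator's contract is to *emulate* the calibrated population;
* covariates are independent by construction (only marginals are
  published); SBP > DBP is enforced by redrawing violating pairs. Real
  age–BMI–BP correlations are therefore **not** reproduced, and no test
  should be read as validating cross-covariate structure.

## QC-RLSC

For each feature and each analytical run, the correction curve is fitted
to the (non-conditioning) QC peak areas against injection order:

1. robust LOESS (tricube weights, local **linear** fit,
   `family = "symmetric"` with two robustifying iterations) — the fit must
   track systematic drift while robustly ignoring random measurement
   error;
2. the span is chosen per feature by leave-one-out cross-validation over
   the grid {0.3, 0.5, 0.75, 1.0}, ties broken toward the smoother span.
   A fixed span cannot serve both a 15-QC UPLC run and wigglier drift
   shapes;
3. a natural cubic spline is interpolated through the LOESS values at the
   QC positions to define the curve at every injection of the run;
   beyond the terminal QCs the curve is held constant (splines extrapolate
   violently at run edges);
4. every cell is divided by the curve at its position. Conditioning QCs
   never enter the fit (they equilibrate the column) but are corrected for
   audit.

Degenerate inputs: fewer than `min_points = 4` usable QC points flags the
feature *uncorrectable* for that run and its values become missing for
that batch, the same convention as a feature undetected in a batch. A
constant QC series short-circuits to a flat curve (robust LOESS is
numerically fragile when all residuals are zero). A fitted curve that
touches zero or goes negative falls back to a flat curve at the run's
median QC area, flagged.

Correction is multiplicative (division), never subtractive: the
un-normalization step — multiplying the concatenated normalized values by
the feature's **median raw QC peak area across all batches** — is only
coherent for a ratio scale. On drift-free noise-free data the two steps
cancel exactly (the identity test asserts a maximum relative deviation
below $10^{-9}$). Because LOESS smooths rather than interpolates, noiseless
*drifted* QCs land near, not exactly on, 1 after correction; the tests
bound that smoothing bias at 2 % for a 30 % exponential drift.

Batches are integrated by matching features across batches within
tolerance (default 10 ppm m/z and 0.2 min retention time for UPLC;
library identity for GC), ambiguities resolved by the nearest-m/z rule;
a feature absent from a batch contributes missing values for that batch's
subjects.

## Filters

Applied in order: (1) post-correction pooled-QC RSD above the platform
tolerance — 20 % for UPLC-MS, 30 % for GC-MS — removes the feature;
(2) presence in fewer than 80 % of subject samples removes it (exactly
80 % is retained); (3) the information ratio, inter-subject RSD divided by
QC RSD, removes features **strictly below 1.5** — a feature whose
biological variation is comparable to its technical variation carries no
usable information. A QC RSD of zero yields an infinite ratio; the feature
is retained and logged. RSD uses the sample ($n-1$) standard deviation,
appropriate for small QC replicate counts. Boundary comparisons carry a
$10^{-9}$ relative guard so that a feature engineered to sit exactly on a
threshold is classified by the documented convention rather than by
floating-point round-off. All filters are idempotent.

## Statistics

Missing cells are mean-imputed per feature (features over 20 % missing
must have been removed by the presence filter and are refused), then each
feature is autoscaled — mean-centred and scaled to unit variance, the
universal metabolomics reading of "normalized to unit variance".
Group screens use the Mann–Whitney U test for two groups (exact for small
untied samples, normal approximation with tie correction otherwise) and
Kruskal–Wallis above two; p-values are reported raw, with an optional
Benjamini–Hochberg flag that is off by default. Two-way ANOVA uses
**Type II** sums of squares — the standard choice for unbalanced
observational designs without strong interactions, and it coincides with
sequential SS on balanced data (tested). Residual degrees of freedom
reflect complete cases, giving the familiar $F(1, 901)$-style reporting.
Tukey HSD post-hoc comparisons use the studentized range; supplying a
covariate factor reproduces the "independent of gender" usage by taking
the residual variance from the additive two-factor model. Correlation
analysis is Pearson on pairwise-complete observations, with rows and
columns ordered by average-linkage hierarchical clustering on
$1 - |r|$ — correlation magnitude, not sign, decides co-membership; the
linkage is configurable since only the technique, not the linkage, is
canonical.

Group boundaries for the clinical hypotheses: age four-category
[min, 40), [40, 50), [50, 65), [65, max]; binary age <50 vs >64; BMI <25
vs >30 (middle excluded); blood pressure normal = systolic 90–120 vs
hypertensive >140 (middle excluded); smoking non/ex/current. Subjects
falling in no bin are excluded from that hypothesis rather than guessed.

## Consensus feature selection

For one hypothesis: each of three ranker families — the vectorised
rank-sum/Kruskal–Wallis statistic, random-forest impurity importance, and
PLS-DA VIP scores (component count fixed at 2 by default, selectable once
by small CV over 2–5) — is fitted on `B = 100` stratified bootstrap
resamples (class counts preserved, so no class can vanish from a
resample), each emitting a full ranking. Rankings are aggregated by Borda
count: a list of $m$ features awards $m - r$ points to the feature at rank
$r$; points are summed, ties broken by mean rank then lexically, with the
tie-broken group recorded. Determinism: one master seed spawns
independent per-ranker streams, and importance ties within a ranker break
lexically by feature id, which also makes the consensus invariant to
feature column order.

Forward selection walks the consensus ranking, training a random forest
(the primary classifier; SVM available) on the top-$k$ features and
estimating accuracy with the 0.632 bootstrap over evaluation resamples
that are **shared across** $k$ — common random numbers keep the
accuracy-vs-$k$ curve smooth so its shape reflects feature addition, not
resampling noise. The optimal $k^\*$ operationalizes "the inflection
point": the smallest $k$ (with a full trailing window) at which the
window-5 moving average of per-feature accuracy gain drops below 0.25
percentage points, capped at `k_max`. Whether such curves should be
judged on held-out bootstrap samples or resubstitution is genuinely open;
the out-of-sample choice is the package's, not a claim about any
particular prior analysis.

## Sample-size study

For each size $n$ in 50–650 (step 50), `B` stratified bootstrap sample
sets of $n$ subjects are drawn with replacement; the classifier is trained
on each set and evaluated on the subjects never drawn into it, and the
median accuracy with a bootstrap-percentile 95 % interval is reported.
The SVM uses a radial kernel with the default bandwidth heuristic and a
cost chosen once from {0.1, 1, 10} by 3-fold CV at the largest size, so
per-size tuning cannot confound the curve. Ranking consistency at size
$n$ is the Spearman correlation between the consensus ranking computed on
a size-$n$ stratified subsample and the full-data consensus ranking; a
requested size equal to the full data uses the data itself, making the
self-comparison exactly 1.

## Problem sizes used by the test suite

The guarantees in `tests/testthat/test-acceptance.R` run at desk scale,
chosen so the whole suite completes in minutes on one core while keeping
each property measurable: drift-removal on 3 batches × 200 features
(attenuation 30–40 %, batch step log-SD 0.35, technical CV 5 % — a drift
level giving pooled pre-correction QC RSD above 25 %); the full-design
layout at 10 batches × 120 subjects × 40 features; selection recovery at
20 informative of 500 features, 1-SD effects, $n = 200$, `B = 50`;
sample-size trends on 800 subjects × 200 features with a joint 2-SD class
separation spread over 20 features (a literal per-feature 2-SD shift
saturates any classifier from $n = 50$ and leaves no learning curve to
measure); oracle equivalence on 1,000 random Borda instances and all
two-group splits of up to 8 observations.

## Limitations

* The simulator starts at the deconvolved peak-area level: no raw
  chromatograms, spectra, adduct/isotope structure, or
  retention-time-dependent matching ambiguity. Cross-batch feature
  matching is therefore easier in simulation than in real XCMS output.
* Cohort covariates are independent; real demographic correlations (and
  their confounding of hypotheses) are not emulated.
* Drift is smooth by construction; abrupt mid-run failures are not
  modelled, and the LOESS span grid assumes at least 4 QC points per run.
* Passing tests demonstrate correct mechanics and recovery under the
  stated generative model — not performance on any particular real
  dataset.
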