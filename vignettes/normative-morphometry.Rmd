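---
title: "Normative morphometry statistics: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative morphometry statistics: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

normorph scores region-wise brain morphometric measurements of an individual
patient — volumes of segmentations, cortical thickness, surface area,
curvature measures, gray–white contrast, whole-brain partial volume
estimates — against a normative database built from healthy-control tables.
This vignette documents the statistical model, every convention with room
for interpretation, and the design decisions that were genuinely open,
together with what the synthetic-data tests do and do not establish.

## The model

For each measurement key (region × hemisphere × parameter × variant) the
control cohort defines a polynomial age trend $X_\mathrm{poly}(a)$ and all
statistics operate on residues $x = X - X_\mathrm{poly}(a)$.

**Quality control.** Values more than 1.5 interquartile ranges outside the
25%/75% percentiles are rejected (Tukey fences), first on the raw values,
then — after a provisional polynomial fit — once more on the fit residues,
and the final fit uses the doubly cleaned data. The two passes run exactly
once each, not iterated to convergence. Quartiles use linear interpolation
between order statistics (`stats::quantile` type 7); this choice is
reproducibility-critical and therefore fixed and documented.

**Degree selection.** Starting from a constant, the degree $d$ grows while
the nested-model F-test
$F = (\mathrm{RSS}_{d-1} - \mathrm{RSS}_d)/(\mathrm{RSS}_d/(N-d-1))$
exceeds the upper $\alpha_\mathrm{fit}/d$ quantile of $F(1, N-d-1)$ — a
per-step Bonferroni correction — up to $d_\mathrm{max} = \lfloor N/20
\rfloor$ (16 at $N = 323$). The per-step (rather than cumulative) Bonferroni
factor is one of two readings of the procedure; the per-step form is
implemented. The provisional fit re-runs the same selection, so residual
rejection is not biased by a fixed provisional degree.
$\alpha_\mathrm{fit}$ defaults to 0.05 and is configurable. Fits are
computed on a centred and scaled age axis for conditioning; coefficients
are reported in natural age units (years).

**Measurement error.** $\sigma_\mathrm{meas}$ per key is the pooled
within-subject SD of residues over subjects rescanned within less than 2
years: $\sqrt{\sum_i\sum_j (x_{ij}-\bar x_i)^2 / \sum_i (k_i - 1)}$. The
pooled unbiased form (denominator $\sum (k_i-1)$) was chosen among the
readings of "mean intra-subject squared error". A subject qualifies when
all their kept scans span under 2 years.

**Artifact model.** Artifact residues are modelled as a zero-centred
Gaussian of width $\sigma_\mathrm{out}$, estimated as the mean absolute
residue of the rejected controls — deliberately *not* rescaled by
$\sqrt{\pi/2}$ to a proper Gaussian SD, following the definition as stated;
the difference is a documented convention. The detectable fraction is
$p_\mathrm{out} = \Phi_{\sigma_\mathrm{out}}(x_<) + 1 -
\Phi_{\sigma_\mathrm{out}}(x_>)$, the artifact probability
$p_\mathrm{art} = (N_\mathrm{out}/N)/p_\mathrm{out}$ (capped at 1, since
the scaling can exceed it for tiny $p_\mathrm{out}$), and the validity odds
$(1-p_\mathrm{art})/p_\mathrm{art}$. With zero observed outliers,
$p_\mathrm{art} = 0$ is only a lower limit and is flagged as such.
$N_\mathrm{out}$ counts rejections from both passes; rejected points'
residues are evaluated against the final fit.

**Visit p-values.** The patient residue is compared with the matched
control subset (exact match on sex, scanner model, acquisition sequence;
minimum size `n_min`, default 10, with an explicit skip rather than a
silent fallback). Variances add: $\sigma^2 = \sigma_\mathrm{norm}^2 +
\sigma_\mathrm{meas}^2$, so measurement error always moves p-values toward
0.5, never toward significance. The per-key reported quantity `p_ucor` is
the tail toward the observation, $1-\Phi_\sigma(x - x_\mathrm{norm})$ above
the mean and $\Phi_\sigma(x - x_\mathrm{norm})$ below it; it lives in
$(0, 0.5]$ and feeds the feature vector $L = -\mathrm{sign}(x -
x_\mathrm{norm})\log_{10} p$.

*Design decision (calibration of significance decisions).* The folded tail
satisfies $P(p_\mathrm{ucor} < \alpha) = 2\alpha$ for normal data, so
thresholding it at $\alpha$ would flag twice the nominal fraction.
Significance decisions — yellow/red highlighting, the FDR family, LOOCV
anomaly counting — therefore use the two-sided p-value
$2\min(p_\mathrm{upper}, 1 - p_\mathrm{upper})$, which is Uniform(0,1)
under the null; "p < α" then flags a fraction α of normal measurements,
which is also what the reference cohort's published cross-validation rates
show at α = 0.05. `visit_pvalue()` exposes all three tail conventions.

**Highlighting.** Yellow marks `p < α` before multiple-comparison
correction — an anomaly that merits secondary expert inspection; red marks
deviations surviving Benjamini–Hochberg FDR over all keys of the dataset
(all variants of one visit form one family; a follow-up series' slope tests
form one family).

**Longitudinal trends.** A linear model $x(t) = a t + x_0$ is fitted to a
patient's residues (their own series first passes the same Tukey-fence
rejection, plus an optional manual exclusion list). With $S^2 =
\mathrm{RSS}/n$ and $\sigma_t^2$ the divide-by-$n$ variance of the visit
times, the slope uncertainty $\Delta a = S/(\sigma_t\sqrt{n-2})$ is
algebraically identical to the classical OLS slope standard error — these
two conventions were chosen precisely because they make the formula exact.
The linear model is accepted when $n S^2/\sigma_\mathrm{meas}^2$ is not in
the upper tail of $\chi^2_{n-2}$ (otherwise the series is not
noise-consistent and the slope is not interpreted), and the slope is tested
against zero with a two-sided z-test. Because residues already subtract the
control age trend, "slope ≠ 0" means "change beyond cross-sectional
aging". Note the z-test's exact null rejection rate on an $n$-visit series
is $2P(t_{n-2} > 1.96)$ — about 8.6% at $n = 10$ — approaching 5% only for
long series; this is a property of the published procedure, not a bug, and
the test suite pins the exact value. Clinical series (EDSS, lesion volume)
use the same trend machinery plus Spearman rank correlation with age; for
$n \le 9$ the Spearman p-value is an exact permutation enumeration (correct
under ties), otherwise the t-approximation.

## The synthetic world

`simulate_cohort()` states the modelled world: 323 subjects, ages uniform
over 7–79 years (the reference cohort's range; its bimodal age histogram is
not emulated — calibration needs coverage, not demographic realism), 56%
female, a Verio/Trio × sequence mix with reference-like weights, 31
subjects rescanned within 0.1–1.9 years, per-key polynomial trends with
intercepts ~100 ± 20 units and slopes up to ±1 unit/year, between-subject
SD 1, measurement SD 0.5, 1% artifact contamination of width 5. Artifacts
*replace* the subject + noise term with a draw from the wide zero-centred
Gaussian, matching the artifact-residue model (they are not offset shifts).
Subject effects are shared across repeat visits so scan–rescan differences
estimate measurement error, not between-subject variance. Keys are
simulated independently; real inter-regional correlation (and its effect on
FDR behaviour) is deliberately not emulated. eTIV is drawn per subject
(sex-specific means) and, by default, does not couple to the measurement
values; a coupling switch exists to exercise the eTIV normalization.

A green calibration test on this world therefore establishes that the
pipeline's statistics behave as designed for independent Gaussian keys with
known confounder structure — it does not establish calibration under real
data's heavy tails, inter-key correlation, or site effects.

## Normalization conventions

eTIV scaling uses the geometric exponents (volumes 1, areas 2/3, thickness
1/3, mean curvature and curvature index −1/3, Gaussian curvature and
folding index −2/3) against the mean control eTIV frozen at database build
time. Contrast normalization is *multiplicative* per scanner–sequence
group — the published description ("normalized to the same mean value")
does not fix additive vs multiplicative; multiplicative was chosen because
contrast is a positive, percentage-like quantity. Patient contrast is
rescaled by their own group's control-derived factor; the factors are never
re-estimated including the patient. Asymmetry indices $(R-L)/(R+L)$ are
computed from raw values (eTIV factors cancel for equal-exponent pairs);
pairs summing to zero yield a missing value.

## LOOCV

`loocv_assess()` removes each held-out subject with *all* their visits
(subject-level LOO, so repeat scans cannot self-match), refits every key's
age trend, rejection bounds, matched statistics and measurement error on
the remainder, and scores the held-out visits exactly like patients. The
eTIV reference and contrast factors are computed once from the full control
set: both are per-key multiplicative scales under which z-scores are
invariant, so they cannot leak; a test cross-checks the lean LOOCV path
against a full `build_normative_db()` + `assess_visit()` rebuild.

On a pure-Gaussian synthetic cohort the observed uncorrected anomaly rates
come out slightly *above* nominal (about 6.3% at α = 0.05 and 1.5% at
α = 0.01 in the shipped calibration runs). This is an inherent, quantified
property of the published procedure, with two causes the test suite
verifies separately: Tukey-fence rejection trims the kept residue SD to
≈ 0.97 of truth, and the matched-subset SD is plugged into a Gaussian
rather than a t tail. The α = 0.01 value in fact reproduces the reference
cohort's own published LOOCV band (1.50–1.74%), which had been attributed
to heavy tails alone.

## Numerical and degenerate-input choices

Missing values are carried explicitly and excluded per key at fit time,
never imputed. Keys with fewer than 4 finite control values are skipped
with a warning; degrees whose kept-point count falls below $d+2$ are not
tested; a perfect fit (RSS = 0) accepts the degree that achieved it and
stops. Constant series give slope 0 and p = 1; a noiseless nonzero trend
gives p = 0. Zero normative spread skips the key. Databases serialize to a
single RDS file whose round trip is bit-exact, with an internal schema
version that refuses mismatched files. All randomness flows from explicit
integer seeds; identical config + seed reproduces output bit-identically.

## Known limitations

The atlas inventory is configurable, not hard-coded — the pipeline accepts
whatever region labels the tables provide. Ages outside the control range
are evaluated with an explicit extrapolation flag and should be treated
with caution. The package deliberately does no image processing: surface
reconstruction, segmentation, lesion filling and eTIV estimation are
upstream concerns, and their outputs are this package's inputs.
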