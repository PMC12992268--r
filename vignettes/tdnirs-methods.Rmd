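---
title: "Methods: from photon time-of-flight to visualized classifiers"
author: "tdnirs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from photon time-of-flight to visualized classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdnirs)
```

This vignette is the package's own account of the science it implements:
the physical model, the two inversion paths, the response-separation and
feature definitions, the statistical layer, the synthetic cohort that
stands in for subject recordings, and the numerical and design choices
made where the methodology is genuinely open.

## The physical model

Light transport in tissue at source–detector separations of a few
centimetres is described by the diffusion approximation. For an
ultrashort pulse injected into a **semi-infinite homogeneous medium**, the
time-resolved diffuse reflectance at separation $\rho$ has the closed form

$$R(\rho, t) \;=\; \frac{1}{2}\,(4\pi D v)^{-3/2}\, t^{-5/2}\,
  e^{-\mu_a v t}\, e^{-\rho^2/(4 D v t)}\,
  \Big[ z_0 e^{-z_0^2/(4Dvt)} + (z_0 + 2 z_b)\, e^{-(z_0+2z_b)^2/(4Dvt)} \Big]$$

with $D = 1/(3\mu_s')$, source depth $z_0 = 1/\mu_s'$, photon speed
$v = c/n$, and extrapolated-boundary distance $z_b = 2AD$ where $A$
follows the standard polynomial fit in the refractive-index mismatch.
`semi_infinite_reflectance()` implements this form (the single-image
zero-boundary variant is selectable; both are classical closed forms, and
the extrapolated boundary is the default because it is the standard
choice for tissue–air interfaces). Two structural properties matter
downstream:

* the solution factorizes as $R(t) = M(t)\, e^{-\mu_a v t}$ with $M$
  independent of absorption, and
* at late times $\mathrm{d}\ln R/\mathrm{d}t \to -(\mu_a v + 5/(2t))$,
  so late photons encode absorption almost purely.

Assumptions inherited by everything built on this model: the medium is
homogeneous (no scalp/skull/cortex layering), $\mu_s'$ and the geometry
are known and fixed within a recording (only $\mu_a$ varies with
hemodynamics; $\mu_s'$ is exposed as a per-subject input because
scattering varies between people), and the instrument response function
is neglected, which is defensible when the delay gates (500 ps) are wide
relative to a typical IRF.

## Delay gates and the two hemodynamic parameter families

`gate_set()` defines three disjoint windows over the photon
time-of-flight axis; the defaults are 500 ps windows starting at 500,
1500 and 2500 ps. Published work of this kind leaves gate timing to
supplements, so the defaults were chosen to sample the early, middle and
late TPSF while staying within the support of a 4 ns histogram; they are
plain arguments, not constants. `gate_tpsf()` sums histogram counts over
whole bins whose centers fall in each window — partial bins are excluded
so the operation is exactly a counting sum.

**Per-delay concentration changes (ΔHbOᵢ, µM).** For each delay $i$ the
optical-density change relative to the pre-task rest,
$\Delta OD_i(\lambda, t) = -\ln\left(I_i(\lambda,t) / \langle I_i(\lambda)
\rangle_{rest}\right)$, is divided by an effective pathlength and the
two-wavelength extinction system
$\Delta OD_i/L_i = \varepsilon \,[\Delta HbO; \Delta HbR]$ is solved per
frame. The pathlength is $L_i = v\,\bar t_i$ with $\bar t_i$ the gate
center: in a time-resolved measurement photon pathlength is proportional
to arrival time, which is exactly the information continuous-wave
instruments lack. The baseline mean of the output is zero by
construction. Channels with nonpositive baseline intensity are flagged
unusable; nonpositive intensities elsewhere become missing frames and are
never interpolated.

**Task-rest ratio (RHbOᵢ, dimensionless).** The ratio of *absolute* HbO
during task to its rest level needs absolute $\mu_a(\lambda, t)$, which
the factorized DE solution provides from a **pair of gates**: with
$G_g(\mu_a) = \int_{gate\ g} M(t)\, e^{-\mu_a v t}\, dt$,

$$\ln\frac{I_a}{I_b} \;=\; \ln\frac{G_a(\mu_a)}{G_b(\mu_a)},$$

whose right-hand side is strictly increasing in $\mu_a$ (the later gate
decays faster). `estimate_mua_from_pair()` tabulates this monotone map on
a fine $\mu_a$ grid (Simpson quadrature over each gate, 801 grid points
to 0.2 mm⁻¹) and inverts it by interpolation. A simpler linear solve that
evaluates $M$ at the gate midpoints is available as
`method = "midpoint"`; it is exact only as gate width → 0 and was
measured at ~8% error on the earliest pair with 500 ps gates (the TPSF is
strongly curved inside gate 1), which is why the integral method is the
default. Solutions at or below a configurable floor (10⁻⁵ mm⁻¹) are
clipped and counted; nonpositive intensity ratios are flagged missing.
Per-frame $(HbO, HbR)$ then follow from $\varepsilon C = \mu_a$, and
$RHbO(t) = HbO(t)/\langle HbO\rangle_{rest}$, with baseline mean 1 by
construction. Any per-channel multiplicative gain cancels twice — in the
gate ratio and in the task/rest ratio — which is the practical appeal of
this parameter: it is insensitive to coupling efficiency and, through
$\mu_s'$ being held per-subject, partially to scattering differences.

The shipped extinction table covers 760 and 850 nm in mm⁻¹ µM⁻¹
(natural-log convention), converted from a standard compilation of
hemoglobin spectra; it is a configurable CSV, and the synthetic generator
uses the same table, so round-trip tests are table-independent.

## Channel rejection

Optode–scalp coupling failures are the dominant artifact in speech-task
recordings. `reject_channels()` applies three deterministic rules:

* **low counts** (counts-based series only): median gated counts per
  frame below 100;
* **baseline instability**: coefficient of variation over the pre-task
  rest above 15%, or a whole-recording linear drift exceeding 10% of the
  median level;
* **saturation/burst**: more than 5% of frames whose residual from a
  running-median smooth (window 5) exceeds 5 robust SDs *and* 5% of the
  median level.

The burst rule deliberately works on residuals from a smooth, with a
relative-magnitude floor: a level-based outlier rule flags the task
deflection itself, and a pure noise-scaled rule misfires at very high
photon counts where the Poisson floor is far below the curvature
residuals of a perfectly clean response. All thresholds are arguments.
Quality is assessed **once per recording** (on counts in photon mode, on
the first ratio family otherwise) and shared across parameter families —
concentration-change series are baseline-zero-mean, where a CV is
undefined — mirroring how coupling losses are reported per recording in
practice.

## Response separation and features

Each retained channel is classified by the sign of its task-window mean
deflection from the rest reference (1 for ratios, 0 for changes):
positive → *activated*, otherwise *suppressive*. The tie resolves to
suppressive, reading "at or below baseline" as a non-positive deflection;
this makes the rule deterministic. Classification is per parameter
family — a channel may be activated in the deep-delay ratio yet
suppressive in the shallow one, and the two families' published response
figures are drawn separately — flagged as a sensitivity-analysis point.
Class means and the channel-averaging response ignore missing frames
pointwise (pairwise-available averaging); an empty class yields a
constant reference curve and a flag that turns its features into missing
values rather than silent zeros.

Two features summarize each response curve over the task window only:

* **integral** — signed trapezoidal area of the deflection (units × s); a
  proxy for response intensity. Suppressive integrals are negative; the
  sign is kept rather than folded into a magnitude, so that group
  contrasts state "deeper suppression" as a more negative mean.
* **centroid** — magnitude-weighted mean time relative to task onset (s);
  a proxy for timing. Weights are absolute deviations so suppressive
  responses carry a meaningful centroid; the result lies in
  [0, task duration] by construction.

The canonical index runs F1–F12 over the two ratio families (activated,
suppressive, channel-averaging × integral, centroid; `feature_index()`),
and D1–D18 over the three per-delay change families.

## Statistics and classifiers

Feature screening is a per-feature two-tailed two-sample t-test at
α = 0.05, Welch by default (group variances are not forced equal; the
pooled Student test is an option). No multiplicity correction is applied
by default — the screen mirrors the raw per-feature reporting convention
of small fNIRS studies and feeds a classifier rather than a confirmatory
claim — with Benjamini–Hochberg behind a flag. Test–retest stability is a
paired two-tailed t-test of each feature between sessions across
subjects; all-zero differences report p = 1 (maximal stability).
Subject × session samples enter group tests as independent rows,
mirroring the two-sessions-as-samples design; this overstates effective n
when sessions correlate, which is why the session comparison is reported
alongside.

Four classifiers cover the visualized-classifier use case: linear SVM
(C = 1), linear discriminant analysis (equal priors — group sizes are
equal by design), a decision tree capped at 3 splits (depth ≤ 2), and
Gaussian naive Bayes, via `MASS`, `e1071` and `rpart`. Features are
z-scored with parameters estimated on training folds only (off for trees,
whose splits are scale-equivariant). Cross-validation is stratified
five-fold with a fixed default seed; rows from the same subject may land
in different folds, matching the samples-as-rows design (a grouped
assignment would be the leakage-aware alternative and is the natural
extension). Reported headline accuracy is resubstitution together with
confusion counts, with CV mean ± SD across fold accuracies reported
separately; the 2D decision boundary is exported as a labeled grid
spanning the observed ranges ± 10%.

## The synthetic cohort

`generate_cohort()` emulates the study conditions the analysis assumes:
two groups of 27 subjects, two sessions each (108 samples), 22 channels,
a 30 s rest / 60 s task / 70 s rest block at 1 Hz, and a 34% per-channel
corruption probability. Responses are difference-of-gamma curves on the
ratio scale (`hrf_curve()`), exactly 1 before onset, peaking `peak_s`
after response onset with a small undershoot, and the peak deflection
equals the amplitude parameter exactly. Each subject draws amplitudes
(lognormal), timings (normal) and a per-channel class assignment;
channels get lognormal response gains. Corrupted channels receive one of
three artifact archetypes — dead coupling, drifting gain, burst spikes —
chosen to exercise every rejection rule. Seeds are counter-based per
subject, so enlarging a cohort never reshuffles existing subjects, and
the session effect is zero by default (test–retest stability is a
programmed property).

Group effect *directions* encode the pattern the pipeline is designed to
detect: the case group has a deeper suppressive response expressed
preferentially in the shallow-delay ratio, and a stronger, earlier
activated response expressed preferentially in the deep-delay ratio
(depth expression via per-family amplitude scalings; suppression is
treated as largely extracerebral, activation as cortical). Effect
*magnitudes* are free parameters of the generator; the defaults
(activation amplitude 0.040 vs 0.053, suppression 0.020 vs 0.027,
activation onset 9 vs 6.5 s, peak 27 vs 23 s, between-subject lognormal
SD 0.40 on amplitudes and 3.5/5 s on timings) were chosen once as a
realistic moderate-separability regime — per-feature t statistics in the
2–4 range and two-feature discriminant CV accuracy around 75% — and are
not tuned per analysis.

Two modes share the same latent curves. `HBO_DIRECT` emits the parameter
families directly with additive frame noise (SD 0.012 ratio units) —
fast, used for replicate-heavy statistical checks. `TPSF` drives
$\mu_a(\lambda, t)$ through the extinction table from the programmed
HbO(t) (rest concentrations 50/20 µM HbO/HbR), evaluates the DE forward
model over 25 ps bins, scales to a photon budget (10⁶ counts/frame
default; a budget whose latest gate expects < 1 count triggers a
warning), and draws Poisson counts — the physics-faithful mode. A
cross-mode test confirms the physics layer does not distort the
programmed structure.

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real recordings: systemic physiology (Mayer waves,
respiration, heartbeat), motion artifacts beyond spike bursts, layered or
heterogeneous optics, instrument response functions (an optional IRF
convolution would stress-test the gating assumption), and any nonlinear
coupling between activation and suppression within a channel. Results on
synthetic cohorts demonstrate internal consistency of the pipeline, not
clinical validity.

## Numerical choices and degenerate inputs

* Gate-pair inversion: tabulated monotone map, interpolated inverse;
  out-of-range ratios clamp to the grid ends; estimates at/below the
  10⁻⁵ mm⁻¹ floor are clipped with a warning count.
* Missing data: frame-level missing values propagate unfiltered until
  response averaging, which is pairwise-available; features from curves
  with under two finite task frames (or zero centroid weight) are
  missing, never imputed.
* Degenerate t-tests: both groups constant and equal → p = 1; constant
  but unequal → p = 0, flagged degenerate.
* Zero-variance features abort boundary grids with the feature named;
  training folds with one class abort CV with guidance to stratify.
* Classification tie at the reference → suppressive (documented above).
* Problem sizes in the test-suite and acceptance script (chosen as the
  package's own validation design): 200 replicate null cohorts
  (14 + 14 subjects, 12 channels) for selection-rate calibration, 40
  default-size cohorts for effect-direction reproduction, 25 for the
  discriminant-accuracy band, 50 label permutations for the chance check.

## Known limitations

The homogeneous semi-infinite model ignores superficial contamination by
construction — the very phenomenon the activated/suppressive separation
is meant to handle empirically — so depth claims rest on gate timing, not
on a layered reconstruction. The μₐ inversion assumes μₛ′ known per
subject; misspecified scattering biases absolute concentrations, though
the task/rest ratio absorbs a constant bias. The per-family channel
classification doubles the number of response definitions and is the main
sensitivity-analysis axis. And with 108 samples, five-fold CV has wide
fold-to-fold variance (± several percent), which is visible in the
reported SDs and is the reason low-dimensional feature sets are
preferred.
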