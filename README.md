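# tdnirs

Analysis pipeline for **time-domain functional near-infrared spectroscopy
(TD-fNIRS)** recordings of block-design cognitive tasks, aimed at studies
that characterize prefrontal hemodynamic patterns — for example
distinguishing people with major depressive disorder from healthy
controls during a verbal fluency task.

TD-fNIRS instruments record, per channel and wavelength, the distribution
of photon times of flight after an ultrashort light pulse (the temporal
point spread function, TPSF). Because late-arriving photons travel deeper,
time-gating the TPSF yields intensity channels with graded depth
sensitivity. `tdnirs` turns those gated intensities into hemodynamic
parameters, separates response patterns, extracts compact features, and
evaluates small visualized classifiers:

1. **Gating** — counts are integrated within three delay gates
   (`gate_tpsf()`), i = 1, 2, 3.
2. **Hemodynamics** — two parameter families per recording:
   * ΔHbOᵢ (µM): per-delay oxyhemoglobin change by the modified
     Beer–Lambert law, ΔOD_i(λ,t) = −ln(I_i(λ,t)/⟨I_i(λ)⟩_rest), with
     delay-specific pathlength L_i = v·t̄_i, solved through the 2×2
     extinction system (`mbll_delta_hbo()`).
   * RHbOᵢ (dimensionless, delay pairs 1–2 and 2–3): absolute task/rest
     HbO ratio. The semi-infinite diffusion model factorizes as
     R(ρ,t) = M(t)·e^(−μₐvt); the intensity ratio between two gates then
     pins down μₐ per frame and wavelength (`estimate_mua_from_pair()`),
     and per-frame (HbO, HbR) follow from ε·C = μₐ, normalized to the
     rest baseline (`rhbo_series()`).
3. **Quality & separation** — channels with poor optode–scalp coupling are
   rejected by explicit rules (`reject_channels()`); retained channels are
   split into *activated* (task-window mean above the rest reference) and
   *suppressive* responses, and averaged per class
   (`build_response_triplet()`).
4. **Features** — per response curve, the signed task-window **integral**
   (response intensity) and the magnitude-weighted **centroid** time
   (response timing); canonical names F1–F12 for the two ratio families
   (`feature_index()`), e.g. F3 = integral of suppressive RHbO₁,
   F7 = integral of activated RHbO₂.
5. **Statistics & classification** — two-tailed Welch t-test selection at
   α = 0.05 (`select_features()`), paired test–retest session comparison
   (`test_retest_compare()`), and four classifiers (linear SVM, LDA,
   depth-limited decision tree, Gaussian naive Bayes) with stratified
   five-fold cross-validation and exportable 2D decision boundaries
   (`fit_predict()`, `boundary_grid()`).

Because raw subject recordings of this kind are rarely shareable, the
package ships a **synthetic cohort generator** (`generate_cohort()`) that
emulates the study design — two groups × two sessions, 22 channels,
block-design task, activated/suppressive channel classes, depth-graded
effect directions, Poisson photon noise at TPSF level, and a configurable
channel-corruption rate — with full ground truth, so every stage of the
pipeline is testable end to end.

## Worked example

Simulate a cohort at the default study conditions (27 subjects per group,
two sessions, 22 channels, 34% channel corruption), run the full pipeline,
and fit a 2D discriminant classifier on the activated deep-delay features:

```r
library(tdnirs)

cfg <- run_config(seed = 7, out_dir = file.path(tempdir(), "run7"),
                  cohort = cohort_spec(seed = 7),
                  classifiers = list(classifier_spec("lda", c("F7", "F8"))))
res <- run_pipeline(cfg)

cat("mean rejected channels per recording:",
    round(mean(res$features$n_rejected), 1), "\n")
ratio_sel <- subset(as.data.frame(res$selection),
                    selected & grepl("^F", feature))
print(ratio_sel[, c("feature", "mean_HC", "mean_MDD", "t", "p")],
      digits = 3, row.names = FALSE)
res$reports[["lda.F7_F8"]]
```

```
mean rejected channels per recording: 7.1
 feature mean_HC mean_MDD     t        p
      F1   0.761    1.144 -6.55 2.17e-09
      F2  35.105   33.336  2.66 9.04e-03
      F3  -0.672   -0.825  2.60 1.07e-02
      F6  33.783   31.008  4.21 5.42e-05
      F7   1.251    1.884 -6.25 9.14e-09
      F8  35.698   33.699  2.80 6.08e-03
      F9  -0.401   -0.492  2.50 1.41e-02
     F11   0.628    0.905 -3.42 8.94e-04
     F12  35.331   32.951  3.25 1.57e-03
lda on {F7, F8}: accuracy 79.6% | CV 77.7% +/- 6.9%
  sensitivity 81.5% (TP 44/54), specificity 77.8% (TN 42/54)
```

Reading the output: about 7 of 22 channels per recording are rejected for
coupling artifacts; the selected ratio-scale features show the programmed
group structure (larger activated/suppressive integrals F1/F3/F7 in the
case group — note suppressive integrals are signed negative — and earlier
centroids F2/F6/F8/F12); and the two-feature discriminant classifier
separates the 54-vs-54 samples at roughly three-quarters accuracy under
five-fold cross-validation. The run directory contains `features.csv`,
`selection.csv`, `retest.csv`, `reports/*.json` and the decision-boundary
grid for plotting.

## Documentation

The methods vignette (`vignettes/tdnirs-methods.Rmd`) describes the
diffusion model and its boundary conditions, the two inversion paths and
their assumptions, the rejection rules, the feature definitions, what the
synthetic generator does and does not emulate, and the package's numerical
and design choices.
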