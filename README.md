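# pathaniso

Is traveled distance represented with the same accuracy in every direction?
When people are passively translated in the sagittal plane and asked to
reproduce the distance by pressing a button during a standardized test
translation, the pattern of absolute errors across directions can reveal an
*anisotropy* of the underlying path-integration process — and, with a
backward-pitched body orientation, whether that anisotropy is anchored to
the body or to gravity.

`pathaniso` is an R package plus a scripted analysis workflow for this
question, aimed at researchers in vestibular psychophysics and spatial
cognition. It provides:

* **Motion profiles** — the raised-cosine target translation
  (`target_profile()`, peak acceleration `2πD/T²`) and the standardized
  test translation (half-sinusoid acceleration phase, then constant
  deceleration; `solve_test_profile()` solves the rest-to-rest closure
  `2At₁/π = d(T−t₁)`, `S = At₁T/π` in closed form).
* **A synthetic cohort generator** (`simulate_cohort()`) reproducing the
  within-subject design (2 orientations × 12 directions × 6 distances),
  with folded-normal absolute errors around a chosen anisotropy curve,
  multiplicative participant heterogeneity, and duration-strategy
  responders whose presses ignore the target distance.
* **Exclusion rules** — participant screening by target–response
  correlation and the per-participant ±2 SD trial-outlier rule
  (`screen_participants()`, `remove_outlier_trials()`).
* **Five (an)isotropy error models** fitted as nonlinear mixed-effects
  models by marginal maximum likelihood and compared by AICc
  (`fit_anisotropy()`, `compare_models()`). The horizontal–vertical model
  is `μ(α) = √((w_h cos α)² + (w_v sin α)²)`; refined variants split the
  horizontal (forward/backward) or vertical (up/down) weight; the isotropy
  null is a random-intercept model.
* **Reference-frame test** — body- vs earth-centered coding of the pitched
  condition's error pattern, correlated against the upright pattern
  (`to_body_frame()`, `compare_frames()`).
* **Stimulus-noise audit** — commanded-vs-recorded SNR, Weber-type
  differential thresholds (`ΔI = 0.05·I + 0.03` horizontal,
  `0.19·I^0.60` up, `0.17·I^0.42` down), and the sub-threshold test of
  target–test noise differences (`snr()`, `differential_threshold()`,
  `noise_vs_threshold()`), on recorded or synthetic IMU traces.

See `vignettes/anisotropy-methods.Rmd` for the models, assumptions and
design choices.

## Worked example

The numbered scripts under `analysis/` run the whole workflow and write
their tables under `results/`. A condensed session:

```r
library(pathaniso)

cfg <- cohort_config(seed = 20240501)     # 24 participants, hv truth
tab <- simulate_cohort(cfg)

scr <- screen_participants(tab)
nrow(scr$excluded)                        # 4  (the duration-strategy responders)
cln <- remove_outlier_trials(scr$kept)
cln$removed_fraction                      # 0.045

fits <- lapply(model_variants(), fit_anisotropy,
               table = cln$trials, orientation = "upright")
compare_models(fits)
```

```
   variant k loglik   aicc converged daicc  best indistinguishable
1       hv 4  139.9 -271.8      TRUE 0.000  TRUE              TRUE
2       ud 5  140.1 -270.1      TRUE 1.681 FALSE              TRUE
3       fb 5  140.0 -269.9      TRUE 1.932 FALSE              TRUE
4     fbud 6  140.1 -268.2      TRUE 3.614 FALSE              TRUE
5 isotropy 3  136.1 -266.1      TRUE 5.676 FALSE             FALSE
```

The generative horizontal–vertical model has the lowest AICc; the isotropy
null is the only variant outside the ΔAICc < 4 indistinguishability band.
The fitted weights (`w_h = 0.286 < w_v = 0.331`) recover the generative
ordering — horizontal translations are reproduced more accurately than
vertical ones — with both weights deflated by the outlier rule's truncation
of the error tail (see the vignette). The reference-frame test on the same
cohort:

```r
fr <- compare_frames(cln$trials)
fr$body   # <frame_correlation> body frame:  r(12) = 0.129, p = 0.690
fr$earth  # <frame_correlation> earth frame: r(12) = 0.057, p = 0.861
```

Body-frame coding correlates better than earth-frame coding, as it must
when the generative anisotropy rotates with the trunk; at this single-cohort
size the margin is small, and `frame_discrimination_study()` shows the
body-frame coding wins in ~63% of replicate cohorts. The noise audit on
synthetic IMU recordings (`analysis/05_stimulus_noise.R`) finds every
direction's target–test noise difference (≤ 0.0008 m/s²) far below the
lowest differential threshold (0.0235 m/s²): sub-threshold throughout.

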