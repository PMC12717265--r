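# acuitysim

Predict monocular visual acuity (VA, in logMAR) from ocular wavefront
aberrations.

Clinicians and lens designers often need an estimate of the acuity an eye
would achieve under a given optical state — uncorrected, best-corrected, or
through a trial lens — without measuring it letter by letter. `acuitysim`
provides two routes from a standard aberrometry report (the first 36
OSA-indexed Zernike coefficients for a 3 mm pupil, plus age and amplitude
of accommodation, AA) to a predicted VA:

**Functional simulation.** The eye's wavefront
W(ρ,θ) = Σⱼ cⱼ Zⱼ(ρ,θ) defines a complex pupil function
P = A(r)·exp(i2πW/λ) (with Stiles–Crawford apodization
A(r) = 10^(−ρ_sc r²/2)); its Fourier transform gives the point spread
function. A Sloan optotype rendered at logMAR-scaled size is blurred by
this PSF, band-limited to the retinal mosaic, filtered by the neural
transfer function NTF(f) = SCSF(f)/MOTF(f) — a standard contrast
sensitivity model over a mean optical transfer function with age factor
AF = 1 + (age/70)⁴ — and perturbed with Gaussian neural noise. A
recognizer (a small convolutional network, or a Pearson template
correlator) declares each letter recognized or not, and VA is scored by
the clinical line protocol: descend 0.1 logMAR while any of five letters
is recognized, stop at a fully-failed line, final VA = last line + 0.02
per accumulated error.

**Tabular boosting.** Observation rows (Zernike subset, age, gated AA →
measured VA) are built per eye under uncorrected, corrected and nine
defocus-curve conditions, and fitted with least-squares gradient boosting
of regression trees (LSBoost, implemented from scratch) or an XGBoost
adapter. AA is gated to the conditions where accommodation can act
(negative trial-lens defocus). The metrics suite reports MSE, RMSE, MAE,
R², max/min error, and the mode and median of absolute errors, with an
optional one-pass 3σ outlier drop.

A seeded synthetic-cohort generator with a psychometric simulated observer
makes the entire pipeline reproducible offline.

## Worked example

```r
library(acuitysim)

# a synthetic clinical cohort: 135 subjects, both eyes, 11 missing VA cells
cohort <- generate_cohort(135, seed = 11, missing_va = 11)
tab <- build_observation_table(cohort)
attr(tab, "n_built"); nrow(tab)
#> [1] 1755
#> [1] 1744

# 80/20 split, LSBoost on the first 9 Zernike coefficients + age + gated AA
sp <- split_train_test(tab, 0.8, seed = 4)
X  <- observation_features(sp$train, k_zernike = 9, use_aa = TRUE)
Xt <- observation_features(sp$test,  k_zernike = 9, use_aa = TRUE)
model <- fit_lsboost(X, sp$train$va)
evaluate(sp$test$va, predict(model, Xt), outlier_policy = "drop3sigma")
#> <metrics_report> n = 348 (used 338, policy drop3sigma)
#>   MSE 0.0006  RMSE 0.0249  MAE 0.0200  R2 0.9026
#>   MaxE 0.0700  MinE 0.0001  Mode 0.0200  Median 0.0169

round(sort(feature_importance(model), decreasing = TRUE)[1:4], 3)
#>       z4       z3 aa_gated      age
#>    0.684    0.084    0.078    0.074
```

The held-out RMSE of ~0.03 logMAR is about 1.5 letters on an ETDRS chart;
defocus (z4) dominates the importance ranking, with astigmatism, gated
accommodation and age following — the expected physiological ordering.
(On this noise-controlled synthetic cohort errors are smaller than on
clinical data, where reported RMSEs are nearer 0.06–0.08 logMAR.)

Simulating what an eye sees and scoring it:

```r
eye <- apply_defocus_condition(zernike_set(), -1.0)  # 1 D of myopic defocus
img <- simulate_optotype(eye, age = 45, letter = "N", logmar = 0.3,
                         sim_config(noise_seed = 1))
trial <- simulate_protocol(eye, age = 45, recognizer = "correlation",
                           sim_config(noise_seed = 1), seed = 1)
trial
#> <va_trial> final VA -0.20 logMAR (5 errors over 14 lines, all-lines scoring)
```

Note the template correlator is an optimistic observer: its templates are
degraded through the same eye, so identification only requires beating
the nine alternative letters and recognition persists to small sizes.
The trained convolutional recognizer, labeled against actual responses,
is the route that emulates a specific observer.

A thin command-line surface wraps the same functions
(`inst/cli/va-tools.R`): `make-cohort`, `build-dataset`, `train-boost`,
`confusion-metrics`, `simulate-optotype`, `predict-va`.

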