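---
title: "Methods: predicting visual acuity from ocular wavefront aberrations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting visual acuity from ocular wavefront aberrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acuitysim)
```

## The problem

Visual acuity (VA) — the smallest letter a person can recognize, reported in
logMAR — integrates the eye's optics, retinal sampling and neural
processing. `acuitysim` predicts monocular distance VA from per-eye Zernike
aberration coefficients (OSA convention, standardized 3 mm pupil), age and
amplitude of accommodation (AA), by two complementary routes:

1. **A functional simulation**: render a Sloan optotype, blur it with the
   eye's point spread function (PSF), apply retinal sampling and a neural
   transfer function (NTF), add neural noise, classify the result as
   recognized/unrecognized, and score VA with the clinical line protocol.
2. **A tabular regressor**: least-squares gradient boosting of regression
   trees (LSBoost, implemented from scratch here) or an XGBoost adapter,
   trained on Zernike subsets, age and gated AA.

## Optical stage

The wavefront is $W(\rho,\theta)=\sum_j c_j Z_j(\rho,\theta)$ with
unit-variance (ANSI-normalized) Zernike polynomials in OSA single
indexing. The OSA ordering fixes which mode each index denotes; we pair it
with the unit-variance normalization because that is the ophthalmic
standard for reporting coefficients in micrometres of RMS.

The complex pupil function is $P = A(r)\,e^{i 2\pi W/\lambda}$ on the
pupil disc, where $A(r) = 10^{-\rho_{sc} r^2/2}$ models the
Stiles–Crawford effect ($\rho_{sc} = 0.05\ \mathrm{mm^{-2}}$ by default, a
conventional literature value; the effect is named by the method but no
coefficient is pinned, so it is configurable). The PSF is the squared
modulus of the centered Fourier transform of the zero-padded pupil.

Sampling is solved backwards from the image plane: with $N$ grid samples
and pupil pitch $dx$, a PSF pixel subtends $\lambda/(N\,dx)$ radians, so
$dx$ is chosen to land the PSF exactly on the optotype canvas scale
(224 px/degree by default) and no resampling is needed before
convolution. The default grid (256 nominal pupil samples, pad factor 4)
puts about 430 samples across a 3 mm pupil at 555 nm. The simulation
wavelength defaults to 555 nm (photopic peak) even though clinical
aberrometers measure in the near infrared, because the rendered letters
emulate photopic viewing; it is configurable.

Coefficient manipulations mirror clinical conditions:

* *corrected*: second-order terms ($c_3, c_4, c_5$) set to zero;
* *defocus condition* $\Delta$: astigmatism zeroed and
  $c_4 = \Delta r^2 / (4\sqrt{3})$, i.e. defocus measured **relative to
  best correction**, because clinical defocus curves start from the
  best-corrected eye. Positive diopters map to positive $c_4$; the sign
  convention is a flag on `diopter_to_z20()`.

## Neural stage

Contrast sensitivity uses the standard two-lobe model
$\mathrm{SCSF}(f) = \Psi\,\mathrm{sech}[(f/(\varphi f_0))^p] -
a\,\mathrm{sech}(f/(\varphi f_1))$ with the published average-observer
parameters ($\Psi = 373.08$, $f_0 = 4.1726$, $f_1 = 1.3625$ cpd,
$a = 0.8493$, $p = 0.7786$, $\varphi = 1$). The mean optical transfer
function (MOTF) carries an age factor $AF = 1 + (\mathrm{age}/70)^4$.
The printed four-term MOTF expression sums two exponential pairs whose
weights each total 1, which strongly suggests the source formula is a
*product* of those two bracketed factors (the sum equals 2 at zero
frequency); both forms are implemented, the sum being the default for
fidelity to the printed expression and the product available as
`form = "product"`. Because the NTF = SCSF/MOTF is normalized to unit
gain at zero frequency before filtering, the choice affects only the
filter's shape, not the overall image gain — without that normalization
the ~372x zero-frequency gain would saturate every image. Two of the
printed MOTF exponents ($e^{-37f}$, $e^{-360f}$) vanish above ~0.1 cpd;
they are implemented verbatim.

Retinal sampling band-limits the image to the Nyquist frequency of a
120 samples/degree receptor mosaic (foveal cone density; the cited
sampling step names no parameter) with a raised-cosine roll-off, then the
canvas is kept at its original raster — equivalent to an ideal
down/up-sample for band-limited content. It can be disabled or retuned.

Neural noise is i.i.d. Gaussian, zero mean, variance 0.01 on the [0, 1]
intensity scale (images live on [0, 1] throughout; outputs are clipped
back to [0, 1] so every stage yields a displayable, trainable image).

## Optotype geometry and the recognizers

A 0.0 logMAR letter subtends 5 arcmin with stroke width one fifth of its
height; each 0.1 logMAR step scales size by $10^{0.1}$. The canvas is
224×224 px at 224 px/degree (1° field), so the largest protocol letter
(1.0 logMAR, 50 arcmin, 187 px) fits; the source material does not state
the canvas subtense, so this fixed-field choice is an explicit assumption
of the package. Glyphs are programmatic vector approximations on the
Sloan 5×5 grid (no proprietary font file); the geometric contract —
outer size, stroke = height/5, dark-on-light polarity — is what the
tests pin.

Two recognizers are provided. The template-correlation observer compares
a neural image against the ten noise-free letter templates by Pearson
correlation (affine-invariant; a constant image is unrecognized by
convention). The convolutional recognizer follows the stated recipe —
224×224 input, one 3×3/8-filter convolution, batch normalization, ReLU,
2×2 max pooling, a 2-way softmax head — trained with Adam, batch 32, 10
epochs on a 70/15/15 split. Learning rate (1e-3) and seeded He-style
initialization are this package's defaults, recorded in the training
report; batch-norm running statistics are seeded from the first batch.
Ties at probability 0.5 resolve to "unrecognized", the protocol-safe
direction.

## The VA protocol

Five letters per line from 1.0 logMAR down to −0.3 in 0.1 steps; the
trial descends while at least one letter on the line is recognized and
stops at a fully-failed line (or the floor). The final VA is the last
attempted line plus 0.02 logMAR per error, where errors accumulate over
**all** attempted lines. This interpretation (rather than counting only
the terminal line) makes a clean run that then fails a whole line score
exactly the previous line's value, matching clinical letter-by-letter
scoring; the alternative is available behind
`errors_last_line_only = TRUE`. If the floor line still has a
recognition, the trial ends there with the floor as the last attempted
line. Levels are rounded to two decimals to keep line labels exact.

## Tabular route

Observation rows are built per eye and condition: the measured
(uncorrected) coefficients, the corrected version, and — for the dominant
eye only — the nine defocus-curve conditions. AA enters gated: a defocus
row carries the subject's AA only when the trial-lens power is negative
(the eye can accommodate through negative lenses but relaxes for positive
ones). For uncorrected rows the package gates on the sign of the eye's
spherical equivalent, an extension the source rules do not spell out and
which we flag as an assumption. Rows with missing VA are dropped; the
80/20 split takes `floor(0.2 n)` test rows (1744 → 348).

LSBoost is classical least-squares boosting: $F_0 = \bar y$, then each
stage fits a CART tree (greedy exhaustive variance-reduction splits,
leaves predict means) to the residuals and adds it with shrinkage. The
stated method names no hyperparameters, so the defaults — 300 stages,
shrinkage 0.1, depth ≤ 4, ≥ 5 rows per leaf — are this package's
choices, recorded in every fit. Split ties break to the lowest feature
index and smallest threshold, making fits fully deterministic. Feature
importance is the normalized total squared-error reduction per feature;
the XGBoost adapter exposes the same contract with its gain importance.

The metrics suite reports MSE, RMSE, MAE, R², maximum and minimum
absolute error, the mode and the median of absolute errors. The mode is
computed after rounding to the 0.02 logMAR letter quantum (errors are
near-discrete multiples of it), ties toward the smaller value — a
declared rule, not one inferred from the source. The 3σ outlier rule is
one pass: drop errors above three standard deviations of the error
sample itself.

## The synthetic cohort

The generator emulates the structure of the clinical population the
methods assume, so every stage trains and tests offline: ages uniform on
30–65; AA declining with age as $\max(0, 18.5 - 0.3\,\mathrm{age})$ D
plus N(0, 1) jitter (a Hofstetter-like slope); spherical equivalent
N(−1, 2²) D clipped to [−7, +4]; cylinder $-|N(0, 0.75^2)|$;
second-order coefficients derived from the refraction and higher-order
coefficients N(0, 0.03²) µm. Ground-truth VA follows a declared blur
rule: the residual defocus of a condition (compensated by accommodation
up to AA when negative) maps to logMAR at 0.18/D, with half weight for
uncompensated cylinder, a 0.004/year penalty past age 50, a floor of
−0.1, a cap of 1.1, and N(0, 0.02) measurement noise. Letter-level
labels come from a psychometric observer:
$p = 0.1 + 0.9\,\mathrm{logistic}((\mathrm{VA}_{presented} -
\mathrm{VA}_{true})/0.05)$, the 0.1 floor being the guess rate over ten
Sloan letters. All of these constants are fixture parameters declared
here and in the function documentation — plausible for the emulated
population but **not** estimates of any real cohort. Passing tests
therefore demonstrate correctness of the machinery and internal
consistency of the pipeline, not clinical accuracy on real eyes; real
aberration tables, letter-by-letter clinical responses and
device-specific noise are outside what the generator emulates.

Eleven missing-VA cells (the study-scale default) are blanked uniformly
at random among the cells that become observations, exercising the
1755 → 1744 construction path.

## Numerical choices and degenerate inputs

* FFT-based linear convolution pads with the background value (1.0) to
  avoid wrap-around ghosts; PSF kernels are cropped to the canvas and
  renormalized to unit sum so blurring conserves mean intensity.
* The NTF guards against division by MOTF values below 1e-12 (reachable
  only at extreme frequencies) by clamping with a warning.
* Zero-variance responses make R² undefined (NaN with a warning); a
  zero-spread error sample removes no outliers; a constant image is
  unrecognized by the correlation observer.
* Every stochastic step (cohort draws, splits, letter draws, noise,
  recognizer initialization) takes an explicit integer seed.

## Problem sizes used by the tests and the acceptance script

Unit tests run the optical pipeline on a 64 px canvas with a 64-sample
pupil grid, where every property (energy conservation, symmetry,
band-limiting) is scale-free; the full 224 px geometry is exercised by
the recognizer fixture (200 images) and the protocol tests. The boosting
checks use synthetic cohorts of 60–500 subjects; the published dataset
cardinalities (1755/1744/348, 14 700 images) are reproduced at exactly
the study scale, which is cheap because manifests are enumerated without
rendering. These sizes are the package's own verification choices.

## Known limitations

* Sloan glyphs are geometric approximations, adequate for the 5×5
  contract and recognition experiments but not typographically exact.
* The average NTF is population-level; no per-subject calibration is
  attempted (by design).
* Crowding, chromatic aberration, scatter and pupil-diameter rescaling
  of coefficients are out of scope.
* Reproducing the published real-data error tables requires the deposited
  clinical dataset; the package supports running on such a table through
  `read_cohort()` but ships no clinical data.
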