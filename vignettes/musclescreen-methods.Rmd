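---
title: "Methods: biosensor quantification, concentration-response modelling and calcium spike analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biosensor quantification, concentration-response modelling and calcium spike analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musclescreen)
```

## The measurement problem

A transgenic zebrafish line expressing GFP under the control of the *hspb11*
regulatory region reports muscle hyperactivity: chemicals that over-excite
skeletal muscle (acetylcholinesterase inhibitors, sodium-channel activators)
induce the reporter in the trunk (slow muscle and notochord), and the
induction is abolished by the anaesthetic MS-222, i.e. it requires muscle
contraction. Screening with this biosensor requires three computational
stages, which this package implements as reusable, tested components:

1. quantifying reporter intensity per embryo from trunk micrographs,
2. turning per-embryo intensities into a concentration–response analysis
   with an effective-concentration estimate (EC1.5), and
3. quantifying muscle calcium dynamics (spike heights and inter-spike
   intervals) from GCaMP time-lapse traces.

Because no raw screen images or traces are publicly deposited, the package
also ships a first-class synthetic-data generator with programmable ground
truth; every downstream stage is verified against that truth.

## Image quantification

Acquisition produces single RGB micrographs of 1392 × 1040 px at
0.32 µm/px. The per-embryo pipeline is:

* **Grayscale conversion.** RGB is collapsed with the standard luma weights
  (0.2989, 0.5870, 0.1140); a green-channel-only mode is available since the
  signal is GFP. Note the luma weights sum to 0.9999, so a constant image is
  preserved to one part in 10⁴, not exactly.
* **Gaussian smoothing** (`sigma_px = 10`). Implemented as separable
  convolution with a normalised kernel truncated at 5σ and mirror boundary
  handling; 5σ truncation keeps the discrete kernel within ~10⁻⁶ of the
  continuous Gaussian, so closed-form checks (the impulse response peak
  1/(2πσ²)) hold to 10⁻⁵ relative. Smoothing is used *only* to localise the
  region of interest.
* **ROI extraction** (`roi_radius_px = 350` at acquisition scale). The
  centre is the intensity-weighted centroid of the smoothed image after
  subtracting the modal intensity (a 256-bin histogram mode — the background
  level of a mostly-empty field). The ROI is a disc of the given radius
  clipped at the image borders. A uniform image has no signal above
  background and is rejected. Whether thresholding should precede the
  centroid is unknown for the original semi-automatic tool; the simplest
  operator consistent with the stated parameters (σ, r) is used.
* **Statistics.** Minimum, maximum, median, mean, sample standard deviation
  (n − 1) and pixel count are computed over the **original, unsmoothed**
  pixels inside the mask, flattened to a 1-D sample ("linearised"); the
  median uses the midpoint convention. No gamma/LUT linearisation is
  applied — those are microscope acquisition settings, not analysis steps.

Coordinates are 1-based `(row, col)` matrices in R's column-major layout;
masks are logical matrices. Absolute intensity scale cancels downstream
because the response variable is normalised fold induction.

## Fold induction, the ANOVA gate, and concentration–response models

Each embryo's mean ROI intensity is divided by the mean of the
solvent-control (concentration 0) embryos, giving **fold induction** with
control mean exactly 1. Normalisation is per embryo (individual data points
are retained, not per-dose means).

A chemical first passes a **one-way ANOVA gate** across all concentrations
including the control, at the deliberately strict `alpha = 0.001`; failures
are reported as `no_effect` and never modelled. The gate's degenerate cases
are defined explicitly: identical values in all groups give F = 0, p = 1;
perfect separation with zero within-group variance gives F = ∞, p = 0. No
multiple-testing correction is applied across chemicals — each is gated
independently.

Chemicals passing the gate are fitted with the peaked
**Gaussian-in-log-concentration model**

$$y(x) = c + (d - c)\,\exp\!\left(-\tfrac{1}{2}\Big(\frac{\ln x - \ln e}{b}\Big)^2\right)$$

with `c` fixed at 1 (the normalised baseline), peak fold `d` at
concentration `e` (µM) and log-width `b`. This parameterisation was chosen
because it carries exactly the four coefficients b, c, d, e, its baseline is
the natural fixed point after normalisation, and it produces the
non-monotonic (rise-then-fall) curves characteristic of reporter induction
bounded above by overt toxicity. Control observations define the
normalisation and enter the ANOVA, but are excluded from this fit (ln 0 is
undefined).

Fitting is nonlinear least squares (Levenberg–Marquardt via `minpack.lm`)
over a deterministic multi-start grid: every tested concentration as a
candidate `e`, three log-width candidates spanning 10–50 % of the log-dose
range, and the maximum per-dose mean as the `d` start. The best-SSE
converged start wins; reproducibility needs no seeds. Exactly flat data
short-circuits to `d =` the common value with `b`, `e` undefined (they are
unidentifiable there) and a `no_induction` flag. When the Gaussian route
fails — non-convergence, no induction, or no valid EC — the **linear model**
`fold = a0 + a1·x` is fitted by OLS with the control included at `x = 0`
(log10 covariate optional, control excluded there), matching the practice of
estimating the 1.5-fold level by linear regression when no peaked response
is apparent. The fallback policy is configurable (`linear`, `none`,
`force_linear`) because the original decision rule for "no Gaussian-like
response" is not documented.

**EC1.5.** The effect level of 1.5-fold reflects typical control
variability. The Gaussian curve crosses it twice; the package returns the
closed-form **ascending-limb** root

$$\ln x = \ln e - |b|\sqrt{2\ln\frac{d-c}{1.5-c}},$$

the only root meaningful as an effective concentration; it requires
`d ≥ 1.5`, otherwise the result is invalid with reason `peak below effect
level`. For the linear model `x = (1.5 − a0)/a1`, valid only for positive
slope and within 10× the tested range. The inversion is verified against
bisection on the forward curve (10⁻⁸ relative over a 1000-point random
parameter sweep) and by forward evaluation (|y(EC1.5) − 1.5| < 10⁻⁶).

Group comparisons mirror the screen's statistics: Tukey HSD on the pooled
within-group mean square (Tukey–Kramer for unequal n) and the two-sided
Welch t-test with Welch–Satterthwaite degrees of freedom. Zero-variance
corner cases are defined (p = 1 for identical groups; p = 0 with a warning
when means differ with no residual variance).

## Calcium spike analysis

Traces are trunk-muscle GCaMP fluorescence sampled every 2.5 minutes for
16 hours. The detection operator is the package's own documented choice (the
original traces were reduced with generic ImageJ/Fiji processing whose spike
criterion is unreported), and every constant is exposed in the
configuration:

* **Baseline**: running 10th percentile over a 50-minute centred window
  (window shrinks at the trace ends). A low percentile tracks slow drift
  while ignoring sparse positive transients; it is a *lower envelope*,
  sitting ≤ the trace at ≳90 % of samples under Gaussian noise.
* **Spikes**: ΔF = trace − baseline is recentred by its median (a robust
  zero given sparse spikes — this cancels the systematic ~1.28 σ gap between
  a 10th-percentile envelope and the true baseline). The noise scale is
  1.4826 × MAD/√2 of the *first differences* of ΔF; differencing removes
  slowly decaying transient tails that would inflate a direct MAD at high
  spike rates. Spikes are strict local maxima of ΔF above
  `k_mad = 3` noise scales that additionally *rise* by more than the
  threshold above the lower of the two preceding samples — an exponential
  transient passes trivially at onset, whereas a noise bump riding the
  elevated tail of an earlier spike does not. Endpoint samples are excluded;
  a minimum peak separation (default 1 sample) is enforced greedily by
  height.
* **Outputs**: heights are ΔF at the peak in raw fluorescence units
  (Fig-style arbitrary intensity); intervals are differences of adjacent
  peak times, so `#intervals = #peaks − 1` whenever any peak exists. Spikes
  are pooled across embryos within a treatment (event-level pooling, as in
  "n = 89 spikes" style reporting) and compared by the same one-way
  ANOVA + Tukey HSD machinery as the dose–response module.

Results are parameter-dependent by construction — heights and counts move
with `k_mad` and the baseline window — which is why all constants live in
`run_config()` and are logged in the demo manifest.

## The synthetic-data generator

The generator exists so that every stage has programmable ground truth.

**Images.** A stylised trunk (notochord band at 2× the brightness of
chevron muscle stripes, inter-stripe tissue at 0.6×) on a dim background
(level 5). The tissue field is scaled so the mean over the trunk mask is
*exactly* `baseline × fold` — programmed fold inductions are therefore
recoverable to round-off in the noiseless case, and any fixed tissue ratio
would do. Additive Gaussian read noise (clipped at 0) is the default;
Poisson shot noise is available. The default geometry is a quarter-scale
frame (348 × 260 px, ROI radius 87) purely to keep examples and tests
economical; the full acquisition frame is one argument away. The camera's
true noise characteristics and bit depth are unreported, so these defaults
are choices, not facts.

**Dose series.** Programmed folds come from a `gaussian_cr_model` evaluated
at each dose (dose 0 is the solvent control at fold 1, never
log-transformed); per-embryo biological scatter is Gaussian on the fold
scale, pixel noise on the image scale, everything deterministic under one
seed. Images, a metadata CSV and a truth JSON can be written to disk
(16-bit grayscale TIFF).

**Traces.** `baseline + drift·t + Σ spikes + noise`, each spike rising
instantaneously and decaying exponentially (τ = 5 min by default, ~2 frames
at 2.5-min sampling). Poisson-drawn onset times are snapped to the sampling
grid: at 2.5-minute frames the sub-frame onset time is unobservable, so the
generator treats onsets as frame-aligned (two spikes in one frame
superimpose). Amplitudes are Gamma (mean 50, CV 0.3) floored at 25 — five
times the default noise sd — because the generator emulates clearly
supra-threshold muscle transients rather than threshold-straddling events.
The truth records, besides onset times and instantaneous amplitudes, the
*grid-sampled* peak time and height of each spike (the noiseless
above-baseline value at its first sampled frame, overlapping tails
included); that is the honest reference for evaluating a detector that only
ever sees the sampled trace.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: embryo-to-embryo morphological variation, uneven
illumination and autofluorescence gradients, focus drift, partially
overlapping embryos, saturation/clipping at acquisition, non-exponential
calcium decay kinetics, and photobleaching trends beyond a linear drift.
Recovery results on synthetic data bound the pipeline's algorithmic error,
not its robustness to those artefacts.

## Numerical and design notes

* Smoothing mass is conserved exactly (mirror reflection re-buckets kernel
  mass inside the image), so blob totals survive smoothing to 10⁻⁹.
* The histogram-mode background estimate assumes the background is the most
  common intensity; it degrades if the object fills most of the frame.
* `nlsLM` runs with `ftol = ptol = 10⁻¹⁵`, max 500 iterations per start;
  noiseless model data is recovered to 10⁻⁶ relative.
* The Gaussian model is log-shift equivariant: scaling all concentrations
  by k scales ê and EC1.5 by k and leaves b̂, d̂ unchanged (tested).
* Degenerate inputs have defined behaviour throughout: empty masks,
  uniform images, flat traces, zero-variance groups, empty controls and
  missing image files all raise typed errors or documented flags rather
  than NaNs.
* Verification problem sizes (also used by `scripts/acceptance.R`): fold
  recovery on quarter-scale images with folds {1, 1.5, 3} (noiseless, and
  noise sd 5 % of baseline with n = 10/dose); Gaussian recovery from
  (b = 0.8, d = 2.5, e = 5 µM) at 8 log-spaced doses × 30 embryos, noise sd
  0.1, 100 replicate fits; gate calibration over 1000 null datasets of
  4 doses × 30; spike recovery over 100 sixteen-hour traces at rate
  0.02 min⁻¹ and a 200-run two-group null. These sizes give stable
  Monte-Carlo estimates while keeping a full verification run in the
  low minutes on one core.

## Known limitations

* The ROI operator chain of the original semi-automatic tool is only
  summarised in its source; this package implements the simplest chain
  consistent with the stated σ and r, and recovers programmed intensities,
  but pixel-for-pixel agreement with the original MATLAB tool cannot be
  claimed or tested.
* EC1.5 is reported without a confidence interval (none is reported in the
  screen either); a bootstrap would be a natural extension.
* Spike statistics are pooled across embryos, ignoring within-embryo
  correlation — matching the original event-level analysis, but a mixed
  model would be more conservative.
* The automatic Gaussian-vs-linear routing is a heuristic
  (non-convergence / no-induction / invalid EC); borderline peaked
  responses near 1.5-fold can legitimately route either way, which is why
  the policy is configurable.
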