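# musclescreen

Analysis toolkit for a zebrafish **muscle-hyperactivity biosensor screen**:
the *TgBAC(hspb11:GFP)* transgenic line up-regulates a GFP reporter in trunk
muscle when skeletal muscle is over-excited (e.g. by acetylcholinesterase
inhibitors or sodium-channel activators). The package turns the raw readouts
of such a screen — trunk micrographs and GCaMP calcium time-lapse traces —
into effective-concentration estimates and group statistics, and ships a
ground-truthed synthetic data generator so the whole pipeline is testable
without any microscopy data.

It is aimed at toxicologists and imaging scientists who run (or review)
reporter-based chemical screens and want the quantification and statistics
to be reproducible, scriptable components rather than one-off macros.

## What it computes

**Image quantification** — per embryo: grayscale conversion, Gaussian
smoothing (σ = 10 px, for localisation only), disc ROI extraction
(r = 350 px at acquisition scale) centred on the intensity centroid after
modal-background subtraction, and intensity statistics (min, max, median,
mean, sd) over the original pixels in the ROI.

**Concentration–response** — per chemical: fold induction is each embryo's
mean intensity over the solvent-control mean; a one-way ANOVA gate at
p < 0.001 separates inert chemicals; responders are fitted with the peaked
Gaussian-in-log-concentration model

y(x) = c + (d − c)·exp(−½·((ln x − ln e)/b)²),  c fixed at 1,

(peak fold *d* at concentration *e*, log-width *b*), with an OLS linear
fallback when no peaked response is fit. The **EC1.5** — the concentration
producing 1.5-fold induction — is the closed-form ascending-limb root

ln x = ln e − |b|·√(2·ln((d−c)/(1.5−c))).

Tukey HSD (Tukey–Kramer for unequal n) and Welch t comparisons cover the
group-level contrasts.

**Calcium spikes** — per GCaMP trace (2.5-min sampling, 16 h): a running
10th-percentile baseline, MAD-based noise scale, and thresholded
local-maximum detection with an onset-rise criterion yield spike heights
(ΔF above baseline) and adjacent-peak intervals, compared across treatments
by ANOVA + Tukey HSD with event-level pooling.

**Synthetic data** — embryo images whose trunk-mask mean is *exactly*
`baseline × fold`, dose series programmed from any Gaussian
concentration–response curve, and calcium traces with known spike times,
amplitudes and intervals — the ground truth every test is checked against.

## Worked example

Simulate a dose series for an inducing chemical (peak fold 2.5 at 5 µM),
quantify every image, and analyse it end to end:

```r
library(musclescreen)

geom <- image_geometry()                 # quarter-scale frame, 348 x 260 px
cfg  <- run_config(roi_radius_px = 87)   # ROI radius matching that scale

bundle <- simulate_dose_series(
  doses = c(0, 0.3, 1, 3, 10, 30),
  cr_model = gaussian_cr_model(b = 0.8, d = 2.5, e = 5),
  n_per_dose = 10, fold_noise_sd = 0.1, pixel_noise_sd = 5,
  geometry = geom, chemical = "azinphos_like", seed = 42)

records <- quantify_batch(bundle$metadata, images = bundle$images, config = cfg)
analyze_chemical(records, chemical = "azinphos_like", config = cfg)
#> <chemical_report> azinphos_like
#>   ANOVA: F(5, 54) = 363.3, p = 2.934e-40 [pass at alpha = 0.001]
#> <gaussian_cr_model> b=0.7481 c=1 d=2.363 e=5.066 uM  (SSE 0.4003, converged: TRUE)
#>   EC1.5 = 1.756 uM (gaussian model)
#>   verdict: gaussian
```

The ANOVA gate passes (the chemical has a real effect), the fitted peak
(d ≈ 2.36-fold at ê ≈ 5.1 µM) recovers the programmed curve
(d = 2.5, e = 5) from 60 noisy images, and the EC1.5 of ≈ 1.8 µM sits close
to the programmed value of 1.53 µM. An inert chemical (flat response) run
through the same pipeline returns `verdict: no_effect` and is never
modelled.

Spike analysis of a simulated 16-hour trace:

```r
tr <- simulate_calcium_trace(spike_rate_per_min = 0.02, seed = 7)
sp <- detect_spikes(tr$trace)
sp
#> <spike_set> embryo1 (control): 26 spikes, threshold 19.7
head(spikes_table(list(sp)), 3)
#>   embryo_id treatment peak_time_min   height interval_to_next_min
#> 1   embryo1   control           7.5 20.50176                   55
#> 2   embryo1   control          62.5 39.80551                    5
#> 3   embryo1   control          67.5 74.76295                   15
```

Heights are in raw fluorescence units above the estimated baseline;
intervals in minutes. `compare_spike_groups()` then mirrors the screen's
height/interval comparisons across treatments.

`run_demo("out/", seed = 1)` runs the whole pipeline (two chemicals,
quantification, reports, traces, spike comparison) and writes a manifest
with a checksum per artifact; reruns with the same seed are byte-identical.
A thin command-line wrapper with `simulate-images`, `simulate-traces`,
`quantify`, `fit-dr`, `spikes` and `demo` subcommands is installed at
`inst/cli/musclescreen.R`.

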