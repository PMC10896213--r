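---
title: "Quantifying mitotic spindle phenotypes with spindleprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitotic spindle phenotypes with spindleprofiler}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(spindleprofiler)
```

## The measurement problem

The kinesin-8 motor KIF18A normally concentrates at the plus-ends of
kinetochore microtubules, several micrometres from the spindle pole, where
it dampens microtubule dynamics and centres chromosomes on the metaphase
plate. Perturbations of its motor domain — point mutations in the alpha-4
helix or small-molecule inhibitors binding near it — shift the protein
toward the spindle poles and abolish its function: chromosomes scatter
along the spindle axis, spindles lengthen, and chromosomally unstable
cells arrest in mitosis, form multipolar spindles and stop proliferating.

Each of those phenotypes has a standard image- or table-based readout.
This vignette describes how `spindleprofiler` implements them, the
assumptions behind each model, the defaults and why they were chosen, and
what the accompanying synthetic-data generator does and does not emulate.

## Line-scan localization analysis

The localization readout is a *line scan*: an intensity profile sampled
along a line drawn from a spindle pole (the γ-tubulin spot) toward the
spindle centre, conventionally 10 pixels wide. `extract_profile()`
samples at steps of one pixel pitch; at each step it averages `width_px`
bilinearly interpolated samples taken perpendicular to the line, centred
on it — the Fiji wide-line convention, stated explicitly here so results
are dialect-stable across tools. Sub-pixel sampling uses bilinear
interpolation; on axis-parallel lines of width 1 it reduces exactly to
indexed pixel lookup (a property the tests assert).

Each channel is then normalized internally to its own maximum
(`normalize_internal()`), scans are aligned so the reference-channel
(γ-tubulin) maximum sits at position 0 (`align_scans()`), and the aligned
channels are averaged pointwise. Normalization precedes alignment and
averaging, matching the conventional order of operations. Two edge
policies had to be decided where convention is silent:

* grid positions covered by fewer than 50% of scans (configurable) are
  dropped from the mean profile, so sparsely covered flanks cannot
  dominate the average;
* ties in a channel maximum break toward the smaller distance (closest to
  the pole) and are flagged in the output rather than resolved silently.

The primary statistic is `distance_to_max()`: the position of the motor
channel's global maximum on each aligned scan, in micrometres from the
pole. Per-scan distances are the unit of analysis (cohort figures plot
one dot per scan); the distance on the averaged profile is also reported.
In batch use the pole anchor is the global maximum of the 3×3-mean
smoothed pole channel (ties toward the smallest row, then column), since
interactive line drawing is out of scope.

```{r linescan}
spec <- spindle_spec(motor_peak_offset_um = 3.5, noise = "poisson", seed = 42)
r <- render_spindle_image(spec)
poles <- detect_poles(r$image)
scans <- lapply(1:2, function(j) {
  normalize_internal(extract_profile(r$image, poles[j, ], poles[3 - j, ],
                                     length_um = 5))
})
set <- align_scans(scans, reference = "pole")
distance_to_max(set, "motor")
plot(set)
```

## Chromosome alignment: Gaussian FWHM

Chromosome congression is scored from the distribution of DNA (DAPI) or
centromere (ACA) fluorescence along the pole-to-pole axis.
`axis_profile()` measures a boxed region of interest whose width is the
spindle length and whose height is fixed (default 5 µm — the convention
specifies "fixed height" without a value; 5 µm covers a metaphase plate
with margin at typical spindle geometries). The profile is the mean over
the box height at each axial step and is normalized to its maximum.

`fit_gaussian_fwhm()` fits

$$y(x) = b + a\,\exp\!\left(-\frac{(x-\mu)^2}{2\sigma^2}\right)$$

by Levenberg–Marquardt least squares and reports
$\mathrm{FWHM} = 2\sqrt{2\ln 2}\,\sigma$ together with the spindle length
(`measure_spindle_length()`, the Euclidean pole-to-pole distance). Model
choices worth stating:

* an **offset term** `b` is included: even internally normalized profiles
  have a nonzero floor from spindle-wide background, and forcing `b = 0`
  biases σ upward;
* initialization is moment-based (μ₀ = intensity-weighted mean, σ₀ =
  weighted sd, b₀ = min, a₀ = max − min), with box bounds keeping μ and σ
  inside the spindle; this converges from every profile shape the
  generator produces;
* non-convergence is reported as `converged = FALSE` so cells are
  excluded *visibly* from cohort summaries, never dropped silently;
* no smoothing or windowing is applied to the profile before fitting.

The same code path serves DAPI- and ACA-based variants: the channel is a
configuration role, not a separate procedure.

```{r fwhm}
ap <- axis_profile(r$image, poles[1, ], poles[2, ])
fit <- fit_gaussian_fwhm(ap)
fit
plot(ap, fit = fit)
```

Expression controls use `expression_quant()`: mean spindle-ROI signal
minus mean background-ROI signal from the same image, normalized to the
cohort mean (so the normalized cohort mean is 1 by construction).

## Live relocalization: ratio profiles and AUC

In live cells, inhibition opens a gap in motor fluorescence at the
spindle centre that expands poleward within minutes, while signal
accumulates at the poles. The quantification compares one pre-treatment
("initial", default −90 s) and one post-treatment ("final", default
+720 s) frame per cell:

1. `spindle_profile_at()` takes the columnwise mean of a rectangular ROI
   along its long axis, in raw units (no internal normalization — the
   ratio needs commensurate scales; mean vs sum across the ROI height is
   immaterial for a fixed ROI since it cancels in the ratio);
2. `ratio_profile()` resamples both profiles by linear interpolation onto
   a common 0–100% spindle-length grid (default 101 points) and divides
   pointwise. The denominator is floored at 1% of the initial profile's
   mean; floor events are counted and reported per cell rather than
   hidden;
3. `auc()` integrates the ratio over the grid by the trapezoid rule with
   baseline 0, so an unchanged cell scores exactly 100.

AUC changes by less than 0.5% between 101 and 1001 grid points on
generator output, so the default grid is not a resolution bottleneck.

## Counting statistics and proliferation

`condition_counts()` pools per-field (total, mitotic, multipolar) counts;
`mitotic_index()` and `multipolar_fraction()` report pooled percentages
(and per-field values, since figures typically show replicate means).
`chisq_compare()` runs a Pearson chi-squared test on the pooled 2×2 table
of outcome vs rest, without continuity correction — pooled counts here
are in the thousands, where the correction only discards power. Whether
published comparisons were pairwise against control or full-table is
generally ambiguous; pairwise is the default and passing more than two
conditions tests the full k×2 table. Expected cells below 1 set a warning
flag on the result. Mitotic *classification* (rounded/condensed
morphology) is upstream of this package; the module consumes counts or
simulator truth.

`pole_count()` scores multipolarity from images: local maxima of the
smoothed pole channel above 30% of its maximum, separated by at least
2 µm, retained only where the tubulin channel also exceeds its image
median — mirroring the two-channel (γ-tubulin + α-tubulin) scoring rule.

`growth_metrics()` normalizes kinetic cell counts to the first timepoint
per well, computes fold change (final/initial), and divides by the
reference condition's *mean* fold change (not well-paired), matching the
usual "normalized to DMSO control for each experiment" design. A
doubling-time-∞ (arrested) well against a 24 h-doubling control over
120 h gives the closed-form normalized fold change of 1/32 exactly.

## Dose-response: percent inhibition and the 4PL fit

Percent inhibition is the exact control-normalized transform
`100·(pos − sample)/(pos − neg)`; noisy wells may fall outside [0, 100]
and are flagged, never clipped. `fit_4pl()` fits the variable-slope
four-parameter logistic in log₁₀-concentration space,

$$y(c) = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
{1 + 10^{(\log_{10}\mathrm{IC}_{50} - \log_{10} c)\,h}},$$

with top/bottom unconstrained (bounded fits can hide plateau problems;
the fit report carries both so constraint decisions stay visible), hill
slope bounded to [0.1, 10], replicates entering the loss pointwise by
default (averaging first is exposed as an option), and no outlier
rejection. Curves whose observed response spans fewer than 20 percentage
points are flagged "shallow": their IC50 is poorly determined regardless
of fit quality.

```{r dose}
d <- simulate_dose_response(dose_spec(ic50 = 8.2, replicate_sd = 3, seed = 42))
fit4 <- fit_4pl(inhibition_curve(d))
fit4
plot(fit4, curve = inhibition_curve(d))
```

## The synthetic generator: what it emulates, and what it does not

No suitable raw micrographs are publicly deposited, so validation rests
on synthetic data with known ground truth. The image model is a sum of 2D
Gaussian sources on a calibrated pixel grid: isotropic pole spots, a
chromosome band with axial spread σ (so the true FWHM is 2√(2 ln 2)·σ),
one motor peak per pole offset along the axis toward the centre, and an
anisotropic tubulin fan between each pole pair. One number —
`motor_peak_offset_um` — parameterises the plus-end-tip vs pole
localization continuum: ~3.5 µm plays the control phenotype, ~0.4 µm the
inhibited one. Time-lapses multiply the motor channel by a smooth
suppression notch (quartic-exponential, residual fraction `gap_floor`)
whose half-width grows after the treatment frame, while pole motor signal
grows by a gain factor; by construction midzone intensity is
non-increasing and pole intensity non-decreasing after treatment, which
the tests assert.

Defaults were chosen once, as plausible values for fixed-cell imaging of
cultured human cells at high magnification, and are not tuned per
analysis: 0.1 µm pixels (a 100× objective with a typical sCMOS camera),
a 10 µm spindle, pole spot σ 0.3 µm, band σ 1.5 µm, motor peak σ 0.5 µm,
peak amplitudes of a few hundred photons over a background of 20 (peak
SNR ≈ 10–15 under Poisson noise), 30 s frame intervals with the final
analysis frame 12 min post-treatment, 20 fields of ~100 cells for counts,
2 h count intervals over 120 h for growth, and 10-point 4-fold serial
dilutions with duplicate wells for dose-response. Absolute intensity
scales and SNR are not published for this kind of data, so the amplitude
defaults are documented choices rather than measurements. Every generator
takes an explicit integer seed — there is no global-RNG path — and
identical spec + seed reproduces output bit-for-bit; each artifact
carries a manifest recording the truths downstream analyses must recover.

The generator deliberately omits: point-spread-function convolution and
any 3D structure (the metrics operate on single focal-plane images with
both poles in focus), photobleaching, stage drift, chromatic shift,
cell-to-cell shape variation, and segmentation difficulty (anchors come
from a clean pole channel). Passing parameter-recovery tests therefore
demonstrates that the *measurement code* is correct and well-calibrated
on data satisfying its geometric assumptions — not that the pipeline is
robust to focus errors, dense fields or labelling artifacts in real
micrographs. Conversely, the invariances the tests establish (positive
rescaling of intensities, alignment idempotence, grid refinement) hold
for any input, real or synthetic.

## Problem sizes and runtime choices

The test-suite and acceptance-script cohorts are sized so the whole
validation runs in well under a minute on one CPU while keeping Monte
Carlo error far from the tolerances: 200 cells for FWHM recovery (mean
within 5% of truth at peak SNR 10), 100 half-spindle scans per arm for
distance-to-max (group means within 0.2 µm, i.e. two pixels), 20 seeded
reruns for the control-vs-inhibited contrast direction, 9 + 7 cells for
the relocalization cohorts (mirroring typical live-imaging group sizes),
100 replicates for chi-squared type-I calibration, and 100 noisy curves
for IC50 recovery (median error < 15% at 3% replicate noise). Named IC50
settings of 8.2 nM and 41.3 nM — the potencies of two published KIF18A
inhibitors — are used as round-trip fixtures: noiseless simulate-then-fit
recovers them to ≤1%.

## Known limitations

* Pole detection assumes the two (or `n_poles`) brightest smoothed maxima
  are poles; fragmented centrosomes or bright debris would need manual
  coordinates (supported everywhere coordinates are accepted).
* The Gaussian alignment model is unimodal; severely scattered
  chromosomes produce multimodal profiles where FWHM under-describes the
  phenotype (the fit still converges, with inflated σ).
* `ratio_profile()` assumes the ROI tracks the same spindle at both
  timepoints; it rejects ROIs whose lengths differ more than 2-fold but
  cannot detect rotation or drift.
* Statistical comparison beyond the chi-squared counting test
  (Kruskal–Wallis/Dunn, ANOVA/Tukey, Mann–Whitney) is intentionally left
  to standard tools on the tidy per-cell tables the pipeline emits.
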