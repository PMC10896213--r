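# spindleprofiler

Quantification of mitotic spindle fluorescence phenotypes in R.

Cancer cells with chromosomal instability (CIN) depend on the kinesin-8
motor KIF18A: when the motor is mutated or chemically inhibited it
relocalizes from kinetochore-microtubule plus-ends to the spindle poles,
chromosomes fail to congress, spindles lengthen, mitotic index and spindle
multipolarity rise, and proliferation of CIN cells collapses.
`spindleprofiler` implements the image and table quantifications used to
measure each of those phenotypes from multi-channel fluorescence
micrographs and plate-reader tables, for cell biologists characterising
kinesin perturbations or screening mitotic inhibitors.

## What it computes

* **Line-scan localization** — intensity profiles along a 10-pixel-wide
  line anchored at a spindle pole (γ-tubulin peak), internally normalized
  per channel, aligned across cells on the reference peak, and summarised
  by the distance from the pole to the maximum motor signal
  (`extract_profile()`, `normalize_internal()`, `align_scans()`,
  `distance_to_max()`).
* **Chromosome alignment and spindle length** — the DNA or centromere
  intensity distribution along the pole-to-pole axis is fitted with a
  Gaussian `b + a·exp(−(x−μ)²/2σ²)`; the alignment statistic is the full
  width at half maximum, FWHM = 2√(2 ln 2)·σ (smaller = tighter metaphase
  plate), reported with the pole-to-pole spindle length
  (`axis_profile()`, `fit_gaussian_fwhm()`, `measure_spindle_length()`).
* **Expression control** — background-subtracted spindle-ROI intensity,
  normalized to the cohort mean (`expression_quant()`).
* **Live relocalization** — final/initial fluorescence ratio across the
  spindle on a 0–100% spindle-length grid and its area under the curve;
  an unchanged cell has AUC = 100 (`spindle_profile_at()`,
  `ratio_profile()`, `auc()`).
* **Counting statistics** — mitotic index and multipolar-spindle fraction
  from per-field counts, compared between conditions with a Pearson
  chi-squared test on pooled counts (no continuity correction), plus
  image-based spindle-pole counting (`mitotic_index()`,
  `multipolar_fraction()`, `chisq_compare()`, `pole_count()`).
* **Proliferation** — kinetic cell-count curves normalized to the first
  timepoint; per-well fold change normalized to a reference condition
  (`growth_metrics()`).
* **Dose-response** — percent inhibition
  `100·(pos − sample)/(pos − neg)` and a four-parameter logistic
  ("variable slope") fit in log-concentration space yielding the IC50
  (`percent_inhibition()`, `fit_4pl()`).

Because raw micrographs of this kind are rarely deposited, the package
also ships a synthetic-data generator — spindle images built from 2D
Gaussian sources, relocalization time-lapses with an expanding midzone
gap, multinomial field counts, logistic growth curves and 4PL plates —
each paired with a ground-truth manifest so every analysis stage can be
validated by parameter recovery (`spindle_spec()`,
`render_spindle_image()`, `render_timelapse()`,
`sample_population_counts()`, `simulate_growth_curve()`,
`simulate_dose_response()`).

## Worked example

Simulate a control-like cell (motor accumulating 3.5 µm from each pole,
Poisson shot noise), then measure it blind:

```r
library(spindleprofiler)

spec <- spindle_spec(motor_peak_offset_um = 3.5, noise = "poisson", seed = 42)
r <- render_spindle_image(spec)

poles <- detect_poles(r$image)
scan  <- normalize_internal(
  extract_profile(r$image, poles[1, ], poles[2, ], length_um = 5))
distance_to_max(scan, "motor")
#> [1] 3.5

fit_gaussian_fwhm(axis_profile(r$image, poles[1, ], poles[2, ]))
#> <gaussian_fit> FWHM = 3.541 um (sigma = 1.504, center = 5.001, offset = 0.07582, rss = 0.00258)

measure_spindle_length(poles[1, ], poles[2, ])
#> [1] 10
```

The motor peak is recovered 3.5 µm from the pole (an inhibited-like render
with `motor_peak_offset_um = 0.4` reads out near the pole instead), and the
chromosome-band FWHM of 3.54 µm matches the generating σ = 1.5 µm
(2√(2 ln 2)·1.5 = 3.53 µm). The same round trip works for dose-response
tables:

```r
d <- simulate_dose_response(dose_spec(ic50 = 8.2, replicate_sd = 3, seed = 42))
fit_4pl(inhibition_curve(d))
#> <fourpl_fit> IC50 = 9.179 nM, hill = 0.8485, top = 104.1%, bottom = -6.52% (rss = 231, n = 20)
```

With 3%-of-signal replicate noise the fitted IC50 lands within ~12% of the
simulated 8.2 nM; noiseless tables are recovered to better than 0.1%.

## Documentation

The methods vignette (`vignettes/spindle-quantification.Rmd`) describes
the measurement models, the synthetic generator's assumptions and
defaults, the numerical choices (fit bounds, initialization, tie-breaks,
denominator floors), and what the parameter-recovery tests do and do not
establish about real microscope data.
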