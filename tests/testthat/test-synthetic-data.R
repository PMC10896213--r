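# The synthetic generators: rendering geometry, photon conservation,
# determinism, manifest completeness, and the table generators' moments and
# closed forms.

test_that("spec constructors validate their invariants", {
  expect_error(spindle_spec(pole_a = c(7, 4), pole_b = c(7, 4)), "distinct")
  expect_error(spindle_spec(pole_a = c(-1, 4)), "inside")
  expect_error(spindle_spec(dna_band_sigma_um = 0), "sigmas")
  expect_error(spindle_spec(n_poles = 1), "n_poles")
  expect_error(spindle_spec(channel_amplitudes = c(pole = -1, tubulin = 1,
                                                   dna = 1, motor = 1)),
               "amplitudes")
  expect_error(population_spec(p_mitotic = 1.2), "\\[0, 1\\]")
  expect_error(growth_spec(horizon_h = 1, sample_interval_h = 2), "horizon")
  expect_error(dose_spec(top = 0, bottom = 10), "exceed")
  expect_error(dose_spec(concentrations = c(4, 1, 16)), "sorted")
  expect_error(timelapse_spec(n_frames = 1), "n_frames")
})

test_that("background-only render is uniform at the background level", {
  r <- render_spindle_image(spindle_spec(
    channel_amplitudes = c(pole = 0, tubulin = 0, dna = 0, motor = 0),
    background = 50, noise = "none"))
  for (ch in r$image$channels) {
    expect_true(all(channel_matrix(r$image, ch) == 50))
  }
})

test_that("pole spots land at the specified pixels and set the true length", {
  r <- render_spindle_image(spindle_spec(
    image_shape = c(160, 280), pole_a = c(10, 10), pole_b = c(10, 20),
    noise = "none"))
  pol <- channel_matrix(r$image, "pole")
  top2 <- order(pol, decreasing = TRUE)[1:2]
  rows <- (top2 - 1) %% nrow(pol) + 1
  cols <- (top2 - 1) %/% nrow(pol) + 1
  # pixel index = um / pixel_size + 1
  expect_setequal(rows, c(101, 101))
  expect_setequal(cols, c(101, 201))
  expect_equal(r$manifest$true_spindle_length_um, 10)
})

test_that("noiseless channel photon mass matches the analytic Gaussian integral", {
  sp <- spindle_spec(channel_amplitudes = c(pole = 0, tubulin = 0,
                                            dna = 1000, motor = 0),
                     dna_band_sigma_um = 1.5, background = 0,
                     noise = "none")
  r <- render_spindle_image(sp)
  pixel_sum <- sum(channel_matrix(r$image, "dna"))
  analytic <- 1000 * 2 * pi * sp$dna_band_sigma_um *
    sp$dna_band_transverse_sigma_um / sp$pixel_size_um^2
  expect_lt(abs(pixel_sum - analytic) / analytic, 0.01)
})

test_that("identical spec + seed gives bit-identical output; generators leave the global RNG alone", {
  sp <- spindle_spec(noise = "poisson", seed = 42)
  set.seed(999)
  before <- .Random.seed
  r1 <- render_spindle_image(sp)
  expect_identical(.Random.seed, before)
  r2 <- render_spindle_image(sp)
  expect_identical(r1$image$data, r2$image$data)
  expect_identical(sample_population_counts(population_spec(seed = 7)),
                   sample_population_counts(population_spec(seed = 7)))
  expect_identical(simulate_growth_curve(growth_spec(seed = 7)),
                   simulate_growth_curve(growth_spec(seed = 7)))
  expect_identical(simulate_dose_response(dose_spec(replicate_sd = 3, seed = 7)),
                   simulate_dose_response(dose_spec(replicate_sd = 3, seed = 7)))
})

test_that("every artifact carries a complete manifest with finite truths", {
  arts <- list(
    manifest(render_spindle_image(spindle_spec(seed = 1))),
    manifest(render_timelapse(timelapse_spec(base = spindle_spec(seed = 1),
                                             n_frames = 4))),
    manifest(sample_population_counts(population_spec(seed = 1))),
    manifest(simulate_growth_curve(growth_spec(seed = 1))),
    manifest(simulate_dose_response(dose_spec(seed = 1))))
  for (m in arts) {
    expect_s3_class(m, "ground_truth_manifest")
    truths <- unlist(m[grep("^true_", names(m))])
    expect_gt(length(truths), 0)
    expect_true(all(is.finite(truths)))
  }
})

test_that("sources placed outside the image are rejected by name", {
  expect_error(render_spindle_image(spindle_spec(
    pole_a = c(7, 0.2), pole_b = c(7, 14), motor_peak_offset_um = 30)),
    "motor peak")
})

test_that("null-treatment time-lapse frames are bit-identical without noise", {
  tl <- two_frame_timelapse(spindle_spec(noise = "none"),
                            gap_fun = function(t) 0 * t,
                            gain_fun = function(t) 1 + 0 * t)
  expect_identical(tl$frames[[1]]$data, tl$frames[[2]]$data)
})

test_that("the motor gap suppresses the midzone monotonically and gains at poles", {
  sp <- spindle_spec(noise = "none", motor_peak_offset_um = 3.5)
  tl <- render_timelapse(timelapse_spec(
    base = sp, n_frames = 10, treatment_frame = 2,
    gap_halfwidth_um = gap_ramp(0.01, 3), pole_gain = gain_ramp(0.004, 3)))
  mid_px <- round(c(7, 9) / sp$pixel_size_um) + 1
  pole_px <- round(c(7, 4) / sp$pixel_size_um) + 1
  mid <- vapply(tl$frames, function(f)
    channel_matrix(f, "motor")[mid_px[1], mid_px[2]], numeric(1))
  pol <- vapply(tl$frames, function(f)
    channel_matrix(f, "motor")[pole_px[1], pole_px[2]], numeric(1))
  expect_true(all(diff(mid) <= 1e-9))
  expect_true(all(diff(pol) >= -1e-9))
  expect_true(mid[10] < mid[1])
  expect_true(pol[10] > pol[1])
})

test_that("frame timestamps place the final frame 12 min after treatment", {
  tl <- render_timelapse(timelapse_spec(
    base = spindle_spec(noise = "none"), frame_interval_s = 30,
    n_frames = 27, treatment_frame = 3))
  expect_equal(tl$timestamps_s[27], 720)   # 12 min post-treatment
  expect_equal(tl$timestamps_s[3], 0)
  expect_identical(manifest(tl)$gap_halfwidth_um[1:3], c(0, 0, 0))
})

test_that("population counts respect degenerate probabilities and binomial moments", {
  z <- sample_population_counts(population_spec(p_mitotic = 0, seed = 3))
  expect_true(all(z$mitotic == 0) && all(z$multipolar == 0))
  o <- sample_population_counts(population_spec(
    p_mitotic = 1, p_multipolar_given_mitotic = 1, seed = 3))
  expect_identical(o$mitotic, o$total)
  expect_identical(o$multipolar, o$mitotic)
  big <- sample_population_counts(population_spec(
    n_fields = 200, cells_per_field_mean = 100, p_mitotic = 0.1, seed = 11))
  frac <- sum(big$mitotic) / sum(big$total)
  se <- sqrt(0.1 * 0.9 / sum(big$total))
  expect_lt(abs(frac - 0.1), 3 * se)
})

test_that("growth curves follow the logistic closed form", {
  flat <- simulate_growth_curve(growth_spec(doubling_time_h = Inf,
                                            count_noise_cv = 0))
  expect_true(all(flat$count == flat$count[1]))
  exp5 <- simulate_growth_curve(growth_spec(n0 = 100, doubling_time_h = 24,
                                            horizon_h = 120,
                                            count_noise_cv = 0))
  expect_equal(exp5$count[nrow(exp5)], 3200)  # 100 * 2^5
  logi <- simulate_growth_curve(growth_spec(n0 = 100, doubling_time_h = 24,
                                            carrying_capacity = 5000,
                                            count_noise_cv = 0))
  expect_true(all(diff(logi$count) >= 0))
  expect_true(all(logi$count <= 5000))
  closed <- 5000 / (1 + (5000 / 100 - 1) * 2^(-logi$time_h / 24))
  expect_equal(logi$count, closed)
})

test_that("dose-response signals follow the 4PL closed form with controls", {
  d <- simulate_dose_response(dose_spec(top = 1, bottom = 0, ic50 = 10,
                                        hill = 1,
                                        concentrations = c(10, 30, 90, 270,
                                                           810),
                                        replicate_sd = 0))
  at <- function(conc) unique(d$signal[d$role == "sample" &
                                         d$concentration_nM == conc])
  expect_equal(at(10), 0.5)        # c = ic50: midpoint
  expect_equal(at(30), 0.25)       # hill 1, c = 3 ic50
  expect_equal(unique(d$signal[d$role == "pos"]), 1)
  expect_equal(unique(d$signal[d$role == "neg"]), 0)
})

test_that("images and manifests round-trip through TIFF + JSON", {
  r <- render_spindle_image(spindle_spec(seed = 5))
  tf <- tempfile(fileext = ".tif")
  write_spindle_image(r$image, tf)
  back <- read_spindle_image(tf)
  expect_equal(back$channels, r$image$channels)
  expect_equal(back$pixel_size_um, r$image$pixel_size_um)
  expect_lt(max(abs(back$data - r$image$data)) / max(r$image$data), 1e-6)
  mf <- tempfile(fileext = ".json")
  write_manifest(r$manifest, mf)
  m2 <- read_manifest(mf)
  expect_equal(m2$true_spindle_length_um, r$manifest$true_spindle_length_um)
  expect_equal(m2$true_dna_fwhm_um, r$manifest$true_dna_fwhm_um)
  unlink(c(tf, paste0(tf, ".json"), mf))
})
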