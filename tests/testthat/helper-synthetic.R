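# Shared fixture builders. Everything is generated in code at test time;
# nothing is read from disk.

# Trapezoid rule for oracle integrals (independent of package internals).
trapz_test <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n])) / 2
}

# A bare image from explicit channel matrices.
make_image <- function(channels, px = 0.1) {
  spindle_image(channels, pixel_size_um = px)
}

# A single-channel constant image replicated across the four standard roles.
constant_image <- function(value, nr = 40, nc = 60, px = 0.1) {
  m <- matrix(value, nr, nc)
  make_image(list(pole = m, tubulin = m, dna = m, motor = m), px)
}

# Standard noiseless render used by several tests.
base_render <- function(..., seed = 1) {
  render_spindle_image(spindle_spec(noise = "none", seed = seed, ...))
}

# Independent evaluation of the expected (noise-free) source model at
# arbitrary physical points: used as the brute-force oracle for profile
# extraction and the relocalization mask integral. Deliberately written as
# plain per-point loops over sources, not shared with package code.
oracle_sources <- function(spec) {
  mid <- (spec$pole_a + spec$pole_b) / 2
  u <- (spec$pole_b - spec$pole_a) /
    sqrt(sum((spec$pole_b - spec$pole_a)^2))
  list(
    mid = mid, u = u,
    motor_centers = list(spec$pole_a + spec$motor_peak_offset_um * u,
                         spec$pole_b - spec$motor_peak_offset_um * u),
    poles = list(spec$pole_a, spec$pole_b)
  )
}

# Expected motor intensity at one (row_um, col_um) point for a time-lapse
# frame: plus-end peaks times the suppression notch, plus pole accumulation,
# plus background.
oracle_motor_at <- function(pt, spec, gap = 0, gain = 1, gap_floor = 0.05) {
  src <- oracle_sources(spec)
  amp <- spec$channel_amplitudes[["motor"]]
  peak_val <- 0
  for (mc in src$motor_centers) {
    peak_val <- peak_val +
      amp * exp(-sum((pt - mc)^2) / (2 * spec$motor_peak_sigma_um^2))
  }
  axial <- sum((pt - src$mid) * src$u)
  mask <- if (gap > 0) 1 - (1 - gap_floor) * exp(-0.5 * (axial / gap)^4) else 1
  pole_val <- 0
  for (p in src$poles) {
    pole_val <- pole_val +
      amp * exp(-sum((pt - p)^2) / (2 * spec$motor_peak_sigma_um^2))
  }
  mask * peak_val + (gain - 1) * pole_val + spec$background
}

# Columnwise-mean oracle profile across an ROI (rows r0:r1 in pixels) at an
# arbitrary axial position x_um, for the default horizontal spindle.
oracle_roi_profile <- function(x_um, rows_px, spec, gap = 0, gain = 1,
                               px = spec$pixel_size_um) {
  vapply(x_um, function(x) {
    mean(vapply(rows_px, function(r) {
      oracle_motor_at(c((r - 1) * px, x), spec, gap, gain)
    }, numeric(1)))
  }, numeric(1))
}

# A half-spindle line-scan cohort: renders `n_cells` spindles at the given
# motor offset and extracts one scan per half-spindle anchored at the
# detected poles. Returns the per-scan distance-to-max values.
linescan_cohort_distances <- function(n_cells, motor_offset_um, seed0,
                                      noise = "poisson", length_um = 5) {
  dists <- numeric(0)
  for (i in seq_len(n_cells)) {
    r <- render_spindle_image(spindle_spec(
      motor_peak_offset_um = motor_offset_um, noise = noise,
      seed = seed0 + i))
    poles <- detect_poles(r$image)
    for (j in 1:2) {
      sc <- normalize_internal(extract_profile(
        r$image, poles[j, ], poles[3 - j, ], length_um = length_um,
        width_px = 10))
      dists <- c(dists, as.numeric(distance_to_max(sc, "motor")))
    }
  }
  dists
}

# Initial/final frame pair of a two-frame relocalization time-lapse
# (frame 1 pre-treatment, frame 2 at +`t_final_s`).
two_frame_timelapse <- function(base, gap_fun, gain_fun, t_final_s = 720) {
  render_timelapse(timelapse_spec(
    base = base, frame_interval_s = t_final_s, n_frames = 2L,
    treatment_frame = 1L, gap_halfwidth_um = gap_fun, pole_gain = gain_fun))
}
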