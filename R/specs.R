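#' Specification for a synthetic spindle image
#'
#' Describes a single multi-channel "focal-plane" micrograph of a mitotic
#' spindle as a sum of 2D Gaussian sources: one isotropic spot per pole in the
#' pole (gamma-tubulin) channel, a chromosome band of known axial spread in
#' the DNA/centromere channel, one motor (KIF18A) peak per pole placed
#' `motor_peak_offset_um` from that pole along the axis toward the spindle
#' centre, and an anisotropic tubulin fan between each pole pair.  The offset
#' parameterises the plus-end-tip vs pole localization continuum: several
#' microns mimics normal plus-end-tip accumulation, ~0 mimics the
#' pole-accumulated phenotype seen after motor inhibition.
#'
#' Coordinates are `(row, col)` in micrometres; the physical position of the
#' pixel with 1-based array index `(i, j)` is `((i-1), (j-1)) * pixel_size_um`
#' (pixel centres on an integer grid starting at 0 um).
#'
#' @param image_shape integer vector `(rows, cols)` in pixels.
#' @param pixel_size_um pixel pitch in micrometres.
#' @param pole_a,pole_b `(row, col)` positions of the two principal spindle
#'   poles, in micrometres.
#' @param pole_spot_sigma_um standard deviation of each pole spot.
#' @param channel_amplitudes named numeric vector of peak photon counts for
#'   roles `pole`, `tubulin`, `dna`, `motor`.
#' @param dna_band_sigma_um axial standard deviation of the chromosome band;
#'   the true alignment FWHM is `2*sqrt(2*log(2))` times this.
#' @param dna_band_transverse_sigma_um transverse spread of the band.
#' @param motor_peak_offset_um distance of each motor peak from its pole,
#'   along the axis toward the centre.
#' @param motor_peak_sigma_um standard deviation of each motor peak.
#' @param tubulin_transverse_sigma_um transverse spread of the tubulin fan.
#' @param background uniform background photon count added to every channel.
#' @param noise `"none"`, `"poisson"` (photon shot noise on the expected
#'   counts) or `"gaussian"` (additive, with `gaussian_sd`).
#' @param gaussian_sd standard deviation used when `noise = "gaussian"`.
#' @param n_poles total number of poles (`>= 2`); extra poles beyond the
#'   first two are placed off-axis at `>= 45` degrees from the pole-pole axis
#'   and `>= 2` um from every other pole, so multipolar renders are
#'   unambiguous to count.
#' @param seed integer seed; every generator draws through it so identical
#'   spec + seed gives bit-identical output.
#'
#' @return An object of class `spindle_spec`.
#' @seealso [render_spindle_image()]
#' @export
#' @examples
#' sp <- spindle_spec(seed = 1)
#' img <- render_spindle_image(sp)$image
#' dim(img$data)
spindle_spec <- function(image_shape = c(140, 180),
                         pixel_size_um = 0.1,
                         pole_a = c(7, 4),
                         pole_b = c(7, 14),
                         pole_spot_sigma_um = 0.3,
                         channel_amplitudes = c(pole = 400, tubulin = 200,
                                                dna = 300, motor = 250),
                         dna_band_sigma_um = 1.5,
                         dna_band_transverse_sigma_um = 2,
                         motor_peak_offset_um = 3.5,
                         motor_peak_sigma_um = 0.5,
                         tubulin_transverse_sigma_um = 1.2,
                         background = 20,
                         noise = c("poisson", "none", "gaussian"),
                         gaussian_sd = 10,
                         n_poles = 2L,
                         seed = 1L) {
  noise <- match.arg(noise)
  if (length(image_shape) != 2 || any(image_shape < 8))
    stopf("image_shape must be (rows, cols) with both >= 8")
  if (!is_num1(pixel_size_um) || pixel_size_um <= 0)
    stopf("pixel_size_um must be a positive number")
  roles <- c("pole", "tubulin", "dna", "motor")
  if (!all(roles %in% names(channel_amplitudes)))
    stopf("channel_amplitudes must name all of: %s", paste(roles, collapse = ", "))
  channel_amplitudes <- channel_amplitudes[roles]
  if (any(channel_amplitudes < 0)) stopf("channel amplitudes must be >= 0")
  if (!is_num1(background) || background < 0) stopf("background must be >= 0")
  for (s in c(pole_spot_sigma_um, dna_band_sigma_um,
              dna_band_transverse_sigma_um, motor_peak_sigma_um,
              tubulin_transverse_sigma_um)) {
    if (!is_num1(s) || s <= 0) stopf("all sigmas must be > 0")
  }
  if (!is_num1(motor_peak_offset_um) || motor_peak_offset_um < 0)
    stopf("motor_peak_offset_um must be >= 0")
  if (!is_count(n_poles) || n_poles < 2) stopf("n_poles must be an integer >= 2")
  if (!is_count(seed)) stopf("seed must be an integer (no global RNG)")
  extent <- (image_shape - 1) * pixel_size_um
  for (p in list(pole_a = pole_a, pole_b = pole_b)) {
    if (length(p) != 2 || any(p < 0) || any(p > extent))
      stopf("pole coordinates must lie inside the image (0..%.2f, 0..%.2f um)",
            extent[1], extent[2])
  }
  if (isTRUE(all.equal(pole_a, pole_b)) || sqrt(sum((pole_a - pole_b)^2)) == 0)
    stopf("pole_a and pole_b must be distinct")
  structure(list(
    image_shape = as.integer(image_shape), pixel_size_um = pixel_size_um,
    pole_a = as.numeric(pole_a), pole_b = as.numeric(pole_b),
    pole_spot_sigma_um = pole_spot_sigma_um,
    channel_amplitudes = channel_amplitudes,
    dna_band_sigma_um = dna_band_sigma_um,
    dna_band_transverse_sigma_um = dna_band_transverse_sigma_um,
    motor_peak_offset_um = motor_peak_offset_um,
    motor_peak_sigma_um = motor_peak_sigma_um,
    tubulin_transverse_sigma_um = tubulin_transverse_sigma_um,
    background = background, noise = noise, gaussian_sd = gaussian_sd,
    n_poles = as.integer(n_poles), seed = as.integer(seed)
  ), class = "spindle_spec")
}

#' Specification for a synthetic relocalization time-lapse
#'
#' Extends a [spindle_spec()] over time.  Frames up to `treatment_frame`
#' (1-based) show the untreated spindle; afterwards the motor channel is
#' multiplied by a suppression notch of half-width `gap_halfwidth_um(t)`
#' centred on the spindle midpoint (the "gap" that opens at the spindle
#' centre and expands poleward) while motor signal accumulates at the poles
#' with gain `pole_gain(t)`.  `t` is seconds after treatment.
#'
#' @param base a [spindle_spec()].
#' @param frame_interval_s seconds between frames (default 30 s).
#' @param n_frames number of frames (`>= 2`).
#' @param treatment_frame 1-based index of the last pre-treatment frame;
#'   frame `i` carries timestamp `(i - treatment_frame) * frame_interval_s`.
#' @param gap_halfwidth_um function of post-treatment time (s) returning the
#'   suppression half-width in um; must be 0 at `t <= 0` and non-decreasing.
#'   See [gap_ramp()].
#' @param pole_gain function of post-treatment time returning the pole motor
#'   enrichment factor (`>= 1`, non-decreasing); see [gain_ramp()].
#' @param gap_floor residual fraction of motor signal at the centre of a
#'   fully developed gap.
#' @return An object of class `timelapse_spec`.
#' @seealso [render_timelapse()]
#' @export
timelapse_spec <- function(base = spindle_spec(),
                           frame_interval_s = 30,
                           n_frames = 27L,
                           treatment_frame = 3L,
                           gap_halfwidth_um = gap_ramp(rate_um_per_s = 0.004,
                                                       max_um = 3),
                           pole_gain = gain_ramp(rate_per_s = 0.002,
                                                 max_gain = 2.5),
                           gap_floor = 0.05) {
  stopifnot(inherits(base, "spindle_spec"))
  if (!is_num1(frame_interval_s) || frame_interval_s <= 0)
    stopf("frame_interval_s must be > 0")
  if (!is_count(n_frames) || n_frames < 2) stopf("n_frames must be >= 2")
  if (!is_count(treatment_frame) || treatment_frame < 1 ||
      treatment_frame > n_frames)
    stopf("treatment_frame must be in [1, n_frames]")
  stopifnot(is.function(gap_halfwidth_um), is.function(pole_gain))
  if (gap_halfwidth_um(0) != 0) stopf("gap_halfwidth_um(0) must be 0")
  if (!is_num1(gap_floor) || gap_floor < 0 || gap_floor > 1)
    stopf("gap_floor must be in [0, 1]")
  structure(list(base = base, frame_interval_s = frame_interval_s,
                 n_frames = as.integer(n_frames),
                 treatment_frame = as.integer(treatment_frame),
                 gap_halfwidth_um = gap_halfwidth_um,
                 pole_gain = pole_gain, gap_floor = gap_floor),
            class = "timelapse_spec")
}

#' Linear-ramp gap and pole-gain dynamics
#'
#' Convenience constructors for the time-dependence of the treated motor
#' channel: a suppression half-width growing linearly from 0 at treatment,
#' capped at `max_um`, and a pole enrichment factor rising linearly from 1,
#' capped at `max_gain`.  Both are 0-width/unit-gain for `t <= 0`.
#'
#' @param rate_um_per_s,rate_per_s growth rate after treatment.
#' @param max_um,max_gain cap.
#' @return A function of time (seconds post treatment).
#' @export
gap_ramp <- function(rate_um_per_s, max_um) {
  force(rate_um_per_s); force(max_um)
  function(t) pmin(pmax(t, 0) * rate_um_per_s, max_um)
}

#' @rdname gap_ramp
#' @export
gain_ramp <- function(rate_per_s, max_gain) {
  force(rate_per_s); force(max_gain)
  function(t) pmin(1 + pmax(t, 0) * rate_per_s, max_gain)
}

#' Specification for synthetic mitotic/multipolar field counts
#'
#' Emulates scoring random fields of view: per field the total cell count is
#' Poisson, the mitotic count binomial given the total, and the multipolar
#' count binomial given the mitotic count.
#'
#' @param n_fields number of fields of view (default 20, the usual number of
#'   random fields scored per condition).
#' @param cells_per_field_mean Poisson mean of total cells per field.
#' @param p_mitotic probability a cell is mitotic (the mitotic index).
#' @param p_multipolar_given_mitotic probability a mitotic cell has a
#'   multipolar spindle.
#' @param seed integer seed.
#' @return An object of class `population_spec`.
#' @seealso [sample_population_counts()]
#' @export
population_spec <- function(n_fields = 20L, cells_per_field_mean = 100,
                            p_mitotic = 0.05,
                            p_multipolar_given_mitotic = 0.05,
                            seed = 1L) {
  if (!is_count(n_fields) || n_fields < 1) stopf("n_fields must be >= 1")
  if (!is_num1(cells_per_field_mean) || cells_per_field_mean <= 0)
    stopf("cells_per_field_mean must be > 0")
  for (p in c(p_mitotic, p_multipolar_given_mitotic)) {
    if (!is_num1(p) || p < 0 || p > 1) stopf("probabilities must be in [0, 1]")
  }
  if (!is_count(seed)) stopf("seed must be an integer")
  structure(list(n_fields = as.integer(n_fields),
                 cells_per_field_mean = cells_per_field_mean,
                 p_mitotic = p_mitotic,
                 p_multipolar_given_mitotic = p_multipolar_given_mitotic,
                 seed = as.integer(seed)),
            class = "population_spec")
}

#' Specification for a synthetic kinetic proliferation curve
#'
#' Logistic growth sampled at fixed intervals, emulating automated
#' brightfield cell counting every couple of hours until confluency:
#' `N(t) = K / (1 + (K/n0 - 1) * 2^(-t/Td))`, which reduces to exponential
#' doubling when `carrying_capacity = Inf` and to an arrested (constant)
#' population when `doubling_time_h = Inf`.
#'
#' @param n0 initial cell count.
#' @param doubling_time_h population doubling time in hours (`Inf` = arrest).
#' @param carrying_capacity confluency plateau (`Inf` = unbounded).
#' @param sample_interval_h hours between counts (default 2 h).
#' @param horizon_h total assay duration in hours.
#' @param count_noise_cv coefficient of variation of multiplicative
#'   (log-normal, mean 1) counting noise.
#' @param seed integer seed.
#' @return An object of class `growth_spec`.
#' @seealso [simulate_growth_curve()]
#' @export
growth_spec <- function(n0 = 100, doubling_time_h = 24,
                        carrying_capacity = Inf,
                        sample_interval_h = 2, horizon_h = 120,
                        count_noise_cv = 0.05, seed = 1L) {
  if (!is_num1(n0) || n0 <= 0) stopf("n0 must be > 0")
  if (!(is_num1(doubling_time_h) || identical(doubling_time_h, Inf)) ||
      doubling_time_h <= 0)
    stopf("doubling_time_h must be > 0 (Inf allowed)")
  if (!(is_num1(carrying_capacity) || identical(carrying_capacity, Inf)) ||
      carrying_capacity <= 0)
    stopf("carrying_capacity must be > 0 (Inf allowed)")
  if (!is_num1(sample_interval_h) || sample_interval_h <= 0)
    stopf("sample_interval_h must be > 0")
  if (!is_num1(horizon_h) || horizon_h < sample_interval_h)
    stopf("horizon_h must be >= sample_interval_h")
  if (!is_num1(count_noise_cv) || count_noise_cv < 0)
    stopf("count_noise_cv must be >= 0")
  if (!is_count(seed)) stopf("seed must be an integer")
  structure(list(n0 = n0, doubling_time_h = doubling_time_h,
                 carrying_capacity = carrying_capacity,
                 sample_interval_h = sample_interval_h,
                 horizon_h = horizon_h, count_noise_cv = count_noise_cv,
                 seed = as.integer(seed)),
            class = "growth_spec")
}

#' Specification for a synthetic ATPase dose-response table
#'
#' Four-parameter logistic (variable slope) inhibition of endpoint
#' luminescence: `signal(c) = bottom + (top - bottom) / (1 + (c/ic50)^hill)`.
#' `top` plays the uninhibited (positive-control, enzyme + DMSO) plateau and
#' `bottom` the fully inhibited (negative-control, no-enzyme) floor.
#'
#' @param top,bottom plateau signals (`top > bottom`).
#' @param ic50 half-maximal inhibitory concentration, nM.
#' @param hill Hill slope.
#' @param concentrations compound concentrations in nM, strictly positive
#'   and sorted ascending; the default is a 10-point 4-fold serial dilution
#'   bracketing single-digit-nM potency.
#' @param replicate_sd Gaussian replicate noise (signal units).
#' @param n_replicates replicates per concentration and per control.
#' @param seed integer seed.
#' @return An object of class `dose_spec`.
#' @seealso [simulate_dose_response()], [fit_4pl()]
#' @export
dose_spec <- function(top = 100, bottom = 0, ic50 = 8.2, hill = 1,
                      concentrations = 0.1 * 4^(0:9),
                      replicate_sd = 0, n_replicates = 2L, seed = 1L) {
  if (!is_num1(top) || !is_num1(bottom) || top <= bottom)
    stopf("top must exceed bottom")
  if (!is_num1(ic50) || ic50 <= 0) stopf("ic50 must be > 0")
  if (!is_num1(hill) || hill <= 0) stopf("hill must be > 0")
  if (length(concentrations) < 2 || any(concentrations <= 0) ||
      is.unsorted(concentrations, strictly = TRUE))
    stopf("concentrations must be strictly positive and sorted ascending")
  if (!is_num1(replicate_sd) || replicate_sd < 0)
    stopf("replicate_sd must be >= 0")
  if (!is_count(n_replicates) || n_replicates < 1)
    stopf("n_replicates must be >= 1")
  if (!is_count(seed)) stopf("seed must be an integer")
  structure(list(top = top, bottom = bottom, ic50 = ic50, hill = hill,
                 concentrations = as.numeric(concentrations),
                 replicate_sd = replicate_sd,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "dose_spec")
}
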