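# Synthetic spindle image rendering: every channel is a sum of 2D Gaussian
# sources on a calibrated pixel grid, plus a uniform background, with noise
# applied last under the spec's seed. No PSF convolution and no z-stacks --
# the downstream metrics all operate on single focal-plane images.

channel_roles <- c("pole", "tubulin", "dna", "motor")

# Physical (um) coordinate grids for a spec: pixel centres at
# (index - 1) * pixel_size_um.
pixel_grid <- function(spec) {
  list(row_um = (seq_len(spec$image_shape[1]) - 1) * spec$pixel_size_um,
       col_um = (seq_len(spec$image_shape[2]) - 1) * spec$pixel_size_um)
}

# Isotropic 2D Gaussian with peak `amp` at `center` (um, (row, col)).
gauss_iso <- function(grid, center, sigma, amp) {
  dr2 <- (grid$row_um - center[1])^2
  dc2 <- (grid$col_um - center[2])^2
  amp * outer(exp(-dr2 / (2 * sigma^2)), exp(-dc2 / (2 * sigma^2)))
}

# Anisotropic 2D Gaussian with principal axis along unit vector `u`.
gauss_aniso <- function(grid, center, u, sigma_axial, sigma_trans, amp) {
  R <- matrix(grid$row_um - center[1], length(grid$row_um), length(grid$col_um))
  C <- matrix(grid$col_um - center[2], length(grid$row_um), length(grid$col_um),
              byrow = TRUE)
  a <- R * u[1] + C * u[2]
  t <- -R * u[2] + C * u[1]
  amp * exp(-a^2 / (2 * sigma_axial^2) - t^2 / (2 * sigma_trans^2))
}

# Pole placement: the first two poles are the spec's principal pair; extra
# poles sit on a circle of radius L/2 about the spindle midpoint at fixed
# off-axis angles (>= 45 degrees), guaranteeing >= 2 um pairwise separation
# for spindles longer than ~3 um so pole counting stays unambiguous.
pole_positions <- function(spec) {
  poles <- rbind(spec$pole_a, spec$pole_b)
  n_extra <- spec$n_poles - 2L
  if (n_extra > 0) {
    mid <- (spec$pole_a + spec$pole_b) / 2
    axis <- spec$pole_b - spec$pole_a
    L <- sqrt(sum(axis^2))
    u <- axis / L
    v <- c(-u[2], u[1])
    angles <- c(90, -90, 135, -135, 45, -45) * pi / 180
    if (n_extra > length(angles))
      stopf("at most %d extra poles are supported", length(angles))
    for (k in seq_len(n_extra)) {
      th <- angles[k]
      p <- mid + (L / 2) * (cos(th) * u + sin(th) * v)
      poles <- rbind(poles, p)
    }
  }
  rownames(poles) <- NULL
  poles
}

check_inside <- function(spec, pt, what) {
  extent <- (spec$image_shape - 1) * spec$pixel_size_um
  if (any(pt < 0) || any(pt > extent))
    stopf("%s at (%.2f, %.2f) um falls outside the %.1f x %.1f um image",
          what, pt[1], pt[2], extent[1], extent[2])
  invisible(pt)
}

# Expected (noise-free) channel images for a spec; shared by the still and
# time-lapse renderers. Returns list(channels = named list of matrices,
# poles_um, motor_centers, axis info).
expected_channels <- function(spec) {
  grid <- pixel_grid(spec)
  poles <- pole_positions(spec)
  for (i in seq_len(nrow(poles)))
    check_inside(spec, poles[i, ], sprintf("pole source %d", i))
  amp <- spec$channel_amplitudes
  centre <- colMeans(poles)

  pole_ch <- matrix(0, spec$image_shape[1], spec$image_shape[2])
  motor_ch <- pole_ch
  motor_centers <- matrix(NA_real_, nrow(poles), 2)
  for (i in seq_len(nrow(poles))) {
    pole_ch <- pole_ch + gauss_iso(grid, poles[i, ], spec$pole_spot_sigma_um,
                                   amp["pole"])
    to_centre <- centre - poles[i, ]
    nrm <- sqrt(sum(to_centre^2))
    dir <- if (nrm > 0) to_centre / nrm else c(0, 0)
    mc <- poles[i, ] + spec$motor_peak_offset_um * dir
    check_inside(spec, mc, sprintf("motor peak source %d", i))
    motor_centers[i, ] <- mc
    motor_ch <- motor_ch + gauss_iso(grid, mc, spec$motor_peak_sigma_um,
                                     amp["motor"])
  }

  # DNA band: centred between the principal pole pair, axial spread
  # dna_band_sigma_um along the pole-pole axis.
  axis <- spec$pole_b - spec$pole_a
  L <- sqrt(sum(axis^2))
  u <- axis / L
  mid <- (spec$pole_a + spec$pole_b) / 2
  dna_ch <- gauss_aniso(grid, mid, u, spec$dna_band_sigma_um,
                        spec$dna_band_transverse_sigma_um, amp["dna"])

  # Tubulin: an anisotropic fan between every pole pair (so multipolar
  # spindles carry tubulin signal near every pole).
  tub_ch <- matrix(0, spec$image_shape[1], spec$image_shape[2])
  np <- nrow(poles)
  for (i in seq_len(np - 1)) for (j in (i + 1):np) {
    pa <- poles[i, ]; pb <- poles[j, ]
    d <- pb - pa
    len <- sqrt(sum(d^2))
    tub_ch <- tub_ch + gauss_aniso(grid, (pa + pb) / 2, d / len,
                                   len / 4, spec$tubulin_transverse_sigma_um,
                                   amp["tubulin"])
  }

  list(channels = list(pole = pole_ch + spec$background,
                       tubulin = tub_ch + spec$background,
                       dna = dna_ch + spec$background,
                       motor = motor_ch + spec$background),
       poles_um = poles, motor_centers_um = motor_centers,
       mid_um = mid, axis_unit = u, length_um = L)
}

apply_noise <- function(channels, spec) {
  if (spec$noise == "none") return(channels)
  lapply(channels, function(m) {
    v <- switch(spec$noise,
                poisson = rpois(length(m), lambda = pmax(m, 0)),
                gaussian = m + rnorm(length(m), sd = spec$gaussian_sd))
    matrix(as.numeric(v), nrow(m), ncol(m))
  })
}

new_spindle_image <- function(channels, pixel_size_um) {
  arr <- array(0, c(nrow(channels[[1]]), ncol(channels[[1]]), length(channels)),
               dimnames = list(NULL, NULL, names(channels)))
  for (k in seq_along(channels)) arr[, , k] <- channels[[k]]
  structure(list(data = arr, channels = names(channels),
                 pixel_size_um = pixel_size_um),
            class = "spindle_image")
}

#' Assemble a spindle image from channel matrices
#'
#' Wraps user-supplied intensity matrices (e.g. imported from a microscopy
#' file) as a calibrated `spindle_image` consumable by every measurement in
#' the package.
#'
#' @param channels named list of equally sized numeric matrices; names are
#'   the channel roles (`pole`, `tubulin`, `dna`, `motor`, or any subset).
#' @param pixel_size_um pixel pitch in micrometres.
#' @return A `spindle_image`.
#' @export
#' @examples
#' img <- spindle_image(list(pole = matrix(0, 20, 20)), pixel_size_um = 0.1)
spindle_image <- function(channels, pixel_size_um) {
  if (is.null(names(channels)) || any(names(channels) == ""))
    stopf("channels must be a named list of matrices")
  dims <- unique(lapply(channels, dim))
  if (length(dims) != 1) stopf("all channel matrices must share dimensions")
  if (!is_num1(pixel_size_um) || pixel_size_um <= 0)
    stopf("pixel_size_um must be positive")
  new_spindle_image(channels, pixel_size_um)
}

#' Extract one channel of a spindle image as a matrix
#'
#' @param image a `spindle_image`.
#' @param role channel role (`"pole"`, `"tubulin"`, `"dna"`, `"motor"`).
#' @return Numeric matrix of intensities.
#' @export
channel_matrix <- function(image, role) {
  stopifnot(inherits(image, "spindle_image"))
  if (!role %in% image$channels)
    stopf("channel '%s' not present (have: %s)", role,
          paste(image$channels, collapse = ", "))
  image$data[, , role]
}

#' Render a synthetic multi-channel spindle image
#'
#' Renders the spindle described by a [spindle_spec()] and returns the image
#' together with a ground-truth manifest recording the hidden parameters the
#' downstream measurements are expected to recover (pole positions, spindle
#' length, chromosome-band FWHM, motor peak offset).
#'
#' @param spec a [spindle_spec()].
#' @return A list with components `image` (a `spindle_image`: calibrated
#'   `rows x cols x 4` array with channel roles) and `manifest` (a
#'   `ground_truth_manifest`).
#' @export
#' @examples
#' r <- render_spindle_image(spindle_spec(noise = "none", seed = 7))
#' r$manifest$true_spindle_length_um
render_spindle_image <- function(spec) {
  stopifnot(inherits(spec, "spindle_spec"))
  ex <- expected_channels(spec)
  channels <- with_seed(spec$seed, apply_noise(ex$channels, spec))
  image <- new_spindle_image(channels, spec$pixel_size_um)
  manifest <- structure(list(
    kind = "spindle_image",
    spec = spec,
    poles_um = ex$poles_um,
    motor_centers_um = ex$motor_centers_um,
    true_spindle_length_um = ex$length_um,
    true_dna_fwhm_um = fwhm_factor * spec$dna_band_sigma_um,
    true_motor_offset_um = spec$motor_peak_offset_um,
    n_poles = nrow(ex$poles_um)
  ), class = "ground_truth_manifest")
  list(image = image, manifest = manifest)
}

#' Render a synthetic relocalization time-lapse
#'
#' Renders `n_frames` frames of the base spindle.  Frames up to
#' `treatment_frame` are identical in expectation; afterwards the motor
#' channel is suppressed in a notch of half-width `gap_halfwidth_um(t)`
#' around the spindle midpoint (a smooth quartic-exponential notch, residual
#' fraction `gap_floor` at its centre) while motor intensity accumulates at
#' the poles with factor `pole_gain(t)`.  Frame `i` carries timestamp
#' `(i - treatment_frame) * frame_interval_s` seconds.
#'
#' @param spec a [timelapse_spec()].
#' @return A list with `frames` (list of `spindle_image`), `timestamps_s`,
#'   and `manifest` (includes the per-frame gap half-widths and pole gains
#'   actually applied).
#' @export
render_timelapse <- function(spec) {
  stopifnot(inherits(spec, "timelapse_spec"))
  base <- spec$base
  ex <- expected_channels(base)
  grid <- pixel_grid(base)
  # Signed axial coordinate of every pixel relative to the spindle midpoint.
  R <- matrix(grid$row_um - ex$mid_um[1], base$image_shape[1],
              base$image_shape[2])
  C <- matrix(grid$col_um - ex$mid_um[2], base$image_shape[1],
              base$image_shape[2], byrow = TRUE)
  axial <- R * ex$axis_unit[1] + C * ex$axis_unit[2]

  motor_plus_end <- ex$channels$motor - base$background
  amp <- base$channel_amplitudes
  pole_spots <- matrix(0, base$image_shape[1], base$image_shape[2])
  for (i in seq_len(nrow(ex$poles_um)))
    pole_spots <- pole_spots + gauss_iso(grid, ex$poles_um[i, ],
                                         base$motor_peak_sigma_um, amp["motor"])

  timestamps <- (seq_len(spec$n_frames) - spec$treatment_frame) *
    spec$frame_interval_s
  gaps <- numeric(spec$n_frames)
  gains <- numeric(spec$n_frames)
  frames <- vector("list", spec$n_frames)

  frames <- with_seed(base$seed, {
    out <- vector("list", spec$n_frames)
    for (i in seq_len(spec$n_frames)) {
      t_post <- max(timestamps[i], 0)
      g <- if (timestamps[i] > 0) spec$gap_halfwidth_um(t_post) else 0
      gain <- if (timestamps[i] > 0) spec$pole_gain(t_post) else 1
      gaps[i] <- g
      gains[i] <- gain
      mask <- if (g > 0) {
        1 - (1 - spec$gap_floor) * exp(-0.5 * (axial / g)^4)
      } else 1
      motor <- mask * motor_plus_end + (gain - 1) * pole_spots +
        base$background
      channels <- ex$channels
      channels$motor <- motor
      out[[i]] <- new_spindle_image(apply_noise(channels, base),
                                    base$pixel_size_um)
    }
    out
  })

  manifest <- structure(list(
    kind = "timelapse", spec_base = base,
    frame_interval_s = spec$frame_interval_s,
    n_frames = spec$n_frames, treatment_frame = spec$treatment_frame,
    timestamps_s = timestamps,
    gap_halfwidth_um = gaps, pole_gain = gains, gap_floor = spec$gap_floor,
    poles_um = ex$poles_um, mid_um = ex$mid_um,
    true_spindle_length_um = ex$length_um,
    true_motor_offset_um = base$motor_peak_offset_um
  ), class = "ground_truth_manifest")

  list(frames = frames, timestamps_s = timestamps, manifest = manifest)
}

#' @export
print.spindle_image <- function(x, ...) {
  cat(sprintf("<spindle_image> %d x %d px (%.3g um/px), channels: %s\n",
              nrow(x$data), ncol(x$data), x$pixel_size_um,
              paste(x$channels, collapse = ", ")))
  invisible(x)
}

#' @export
print.ground_truth_manifest <- function(x, ...) {
  cat(sprintf("<ground_truth_manifest> kind: %s\n", x$kind))
  truths <- x[grep("^true_", names(x))]
  for (nm in names(truths))
    cat(sprintf("  %s = %s\n", nm, format(truths[[nm]])))
  invisible(x)
}
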