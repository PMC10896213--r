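# Pole-anchored line-scan profiling: extraction with perpendicular width
# averaging, internal normalization, peak alignment on a reference channel,
# averaging across cells, and the distance-from-pole-to-maximum statistic.

new_line_scan <- function(positions_um, intensities, width_px, cell_id,
                          spacing_um, normalized = FALSE) {
  structure(list(positions_um = positions_um, intensities = intensities,
                 width_px = width_px, cell_id = cell_id,
                 spacing_um = spacing_um, normalized = normalized),
            class = "line_scan")
}

#' Extract an intensity profile along a pole-anchored line
#'
#' Samples each requested channel along the line from `anchor` toward
#' `toward`, at steps of one pixel pitch, reporting at each step the mean of
#' `width_px` bilinearly interpolated samples taken perpendicular to the
#' line and centred on it (the Fiji wide-line convention).  Position 0 is
#' the anchor (normally a detected spindle pole; see [detect_poles()]).
#'
#' @param image a `spindle_image`.
#' @param anchor,toward `(row, col)` positions in micrometres; the line runs
#'   from `anchor` in the direction of `toward` for `length_um`.
#' @param length_um line length in micrometres.
#' @param width_px perpendicular averaging width in pixels (default 10, the
#'   conventional wide-line setting).
#' @param channels channel roles to record; default all channels.
#' @param cell_id identifier carried through to outputs.
#' @return A `line_scan`: uniformly spaced `positions_um` starting at 0 and
#'   a named list of intensity vectors.
#' @export
#' @examples
#' r <- render_spindle_image(spindle_spec(noise = "none"))
#' p <- detect_poles(r$image)
#' sc <- extract_profile(r$image, p[1, ], p[2, ], length_um = 5)
#' sc
extract_profile <- function(image, anchor, toward, length_um,
                            width_px = 10L, channels = NULL,
                            cell_id = NA_character_) {
  stopifnot(inherits(image, "spindle_image"))
  if (is.null(channels)) channels <- image$channels
  if (!all(channels %in% image$channels))
    stopf("unknown channel(s): %s",
          paste(setdiff(channels, image$channels), collapse = ", "))
  if (!is_count(width_px) || width_px < 1) stopf("width_px must be >= 1")
  if (!is_num1(length_um) || length_um <= 0) stopf("length_um must be > 0")
  d <- as.numeric(toward) - as.numeric(anchor)
  nrm <- sqrt(sum(d^2))
  if (nrm == 0) stopf("anchor and toward coincide: direction undefined")
  u <- d / nrm
  v <- c(-u[2], u[1])

  px <- image$pixel_size_um
  s <- seq(0, length_um, by = px)
  offsets <- (seq_len(width_px) - (width_px + 1) / 2) * px
  # Sample points: for each arclength, width_px perpendicular offsets.
  ctr_r <- anchor[1] + s * u[1]
  ctr_c <- anchor[2] + s * u[2]
  R <- outer(ctr_r, offsets * v[1], `+`)
  C <- outer(ctr_c, offsets * v[2], `+`)
  # Convert physical um to fractional 1-based pixel indices.
  Ri <- R / px + 1
  Ci <- C / px + 1
  nr <- nrow(image$data); nc <- ncol(image$data)
  oob <- Ri < 1 - 1e-9 | Ri > nr + 1e-9 | Ci < 1 - 1e-9 | Ci > nc + 1e-9
  if (any(oob)) {
    first <- s[which(apply(oob, 1, any))[1]]
    stopf("line leaves the image: first out-of-bounds sample at arclength %.3f um",
          first)
  }
  Ri <- pmin(pmax(Ri, 1), nr); Ci <- pmin(pmax(Ci, 1), nc)
  intensities <- lapply(channels, function(ch) {
    m <- image$data[, , ch]
    vals <- matrix(bilinear_sample(m, as.vector(Ri), as.vector(Ci)),
                   nrow = length(s))
    rowMeans(vals)
  })
  names(intensities) <- channels
  new_line_scan(s, intensities, as.integer(width_px), cell_id, px)
}

#' Normalize a line scan internally to its per-channel maximum
#'
#' Each channel is divided by its own maximum so the normalized maxima are
#' exactly 1; positions are unchanged.  Idempotent, and invariant to
#' positive rescaling of the raw intensities.
#'
#' @param scan a `line_scan`.
#' @return The normalized `line_scan`.
#' @export
normalize_internal <- function(scan) {
  stopifnot(inherits(scan, "line_scan"))
  scan$intensities <- lapply(setNames(names(scan$intensities),
                                      names(scan$intensities)), function(ch) {
    v <- scan$intensities[[ch]]
    m <- max(v)
    if (!is.finite(m) || m <= 0)
      stopf("channel '%s' has no positive signal: cannot normalize", ch)
    v / m
  })
  scan$normalized <- TRUE
  scan
}

scan_argmax_position <- function(scan, channel) {
  v <- scan$intensities[[channel]]
  idx <- which(v == max(v))
  list(position = scan$positions_um[idx[1]], tie = length(idx) > 1)
}

#' Align line scans on the reference-channel peak and average
#'
#' Shifts every scan so the position of its reference-channel maximum
#' (normally the pole / gamma-tubulin channel) is 0, then averages each
#' channel pointwise across scans on the shared pixel-pitch grid.  Grid
#' positions covered by fewer than `min_coverage` of the scans are dropped
#' from the mean profile.
#'
#' @param scans a list of `line_scan` objects (same channels, same spacing).
#' @param reference channel role used for peak alignment (default `"pole"`).
#' @param min_coverage minimum fraction of scans that must cover a position
#'   for it to enter the mean profile.
#' @return An `aligned_scan_set` with shifted `scans`, the per-channel
#'   `mean_profile` (data.frame; first column `position_um`, then one column
#'   per channel, plus `n_scans` coverage), and `n_scans`.
#' @export
align_scans <- function(scans, reference = "pole", min_coverage = 0.5) {
  if (inherits(scans, "line_scan")) scans <- list(scans)
  if (length(scans) < 1) stopf("need at least one scan")
  if (!all(vapply(scans, inherits, logical(1), "line_scan")))
    stopf("scans must be line_scan objects")
  channels <- names(scans[[1]]$intensities)
  for (s in scans) {
    if (!reference %in% names(s$intensities))
      stopf("reference channel '%s' missing from a scan", reference)
  }
  spacing <- scans[[1]]$spacing_um
  shifted <- lapply(scans, function(s) {
    am <- scan_argmax_position(s, reference)
    s$positions_um <- s$positions_um - am$position
    s
  })
  # Pool on an integer grid (positions are multiples of the pixel pitch up
  # to float error), averaging per position.
  idx_of <- function(s) as.integer(round(s$positions_um / spacing))
  all_idx <- sort(unique(unlist(lapply(shifted, idx_of))))
  n <- length(all_idx)
  sums <- matrix(0, n, length(channels), dimnames = list(NULL, channels))
  cov <- integer(n)
  for (s in shifted) {
    pos <- match(idx_of(s), all_idx)
    cov[pos] <- cov[pos] + 1L
    for (ch in channels) sums[pos, ch] <- sums[pos, ch] + s$intensities[[ch]]
  }
  keep <- cov >= min_coverage * length(shifted)
  mean_profile <- data.frame(position_um = all_idx[keep] * spacing)
  for (ch in channels) mean_profile[[ch]] <- sums[keep, ch] / cov[keep]
  mean_profile$n_scans <- cov[keep]
  structure(list(scans = shifted, alignment_channel = reference,
                 mean_profile = mean_profile, n_scans = length(shifted),
                 min_coverage = min_coverage, spacing_um = spacing),
            class = "aligned_scan_set")
}

#' Distance from the pole to the maximum of a target channel
#'
#' For a single aligned scan, returns the position (micrometres; 0 is the
#' reference/pole peak) of the global maximum of the target channel.  Ties
#' are broken toward the smaller distance, i.e. closest to the pole, and
#' flagged in the result.  For an [align_scans()] set, per-scan distances
#' are the primary statistic and the distance on the mean profile is also
#' reported.
#'
#' @param x a `line_scan` or `aligned_scan_set`.
#' @param target channel role whose peak is located (default `"motor"`).
#' @return For a `line_scan`: a number with attribute `tie`.  For an
#'   `aligned_scan_set`: a `distance_to_max` object with `per_scan`,
#'   `mean_profile_distance`, `ties`.
#' @export
#' @examples
#' r <- render_spindle_image(spindle_spec(noise = "none",
#'                                        motor_peak_offset_um = 3))
#' p <- detect_poles(r$image)
#' sc <- normalize_internal(extract_profile(r$image, p[1, ], p[2, ], 5))
#' distance_to_max(sc, "motor")
distance_to_max <- function(x, target = "motor") UseMethod("distance_to_max")

#' @export
distance_to_max.line_scan <- function(x, target = "motor") {
  if (!target %in% names(x$intensities))
    stopf("target channel '%s' not present", target)
  v <- x$intensities[[target]]
  if (diff(range(v)) == 0)
    stopf("target channel '%s' is flat: no unique maximum", target)
  am <- scan_argmax_position(x, target)
  structure(am$position, tie = am$tie)
}

#' @export
distance_to_max.aligned_scan_set <- function(x, target = "motor") {
  per <- lapply(x$scans, distance_to_max, target = target)
  mp <- x$mean_profile
  if (!target %in% names(mp)) stopf("target channel '%s' not present", target)
  v <- mp[[target]]
  if (diff(range(v)) == 0)
    stopf("mean profile of '%s' is flat: no unique maximum", target)
  idx <- which(v == max(v))
  structure(list(per_scan = vapply(per, as.numeric, numeric(1)),
                 ties = vapply(per, function(d) isTRUE(attr(d, "tie")),
                               logical(1)),
                 mean_profile_distance = mp$position_um[idx[1]],
                 target = target),
            class = "distance_to_max")
}

#' @export
print.line_scan <- function(x, ...) {
  cat(sprintf("<line_scan> %s%d positions, 0-%.2f um (step %.3g), width %d px, channels: %s\n",
              if (is.na(x$cell_id)) "" else paste0(x$cell_id, ": "),
              length(x$positions_um), max(x$positions_um), x$spacing_um,
              x$width_px, paste(names(x$intensities), collapse = ", ")))
  if (x$normalized) cat("  internally normalized (per-channel max = 1)\n")
  invisible(x)
}

#' @export
print.aligned_scan_set <- function(x, ...) {
  cat(sprintf("<aligned_scan_set> %d scans aligned on '%s' peak; mean profile over %d positions (coverage >= %d%%)\n",
              x$n_scans, x$alignment_channel, nrow(x$mean_profile),
              round(100 * x$min_coverage)))
  invisible(x)
}

#' @export
print.distance_to_max <- function(x, ...) {
  cat(sprintf("<distance_to_max> target '%s': per-scan mean %.3f um (n = %d), on mean profile %.3f um\n",
              x$target, mean(x$per_scan), length(x$per_scan),
              x$mean_profile_distance))
  if (any(x$ties)) cat(sprintf("  %d scan(s) had tied maxima (broken toward the pole)\n",
                               sum(x$ties)))
  invisible(x)
}

#' @export
plot.aligned_scan_set <- function(x, channels = NULL, ...) {
  mp <- x$mean_profile
  if (is.null(channels))
    channels <- setdiff(names(mp), c("position_um", "n_scans"))
  cols <- seq_along(channels) + 1
  plot(range(mp$position_um), c(0, max(unlist(mp[channels]))), type = "n",
       xlab = "distance from reference peak (um)", ylab = "mean intensity",
       ...)
  for (i in seq_along(channels))
    lines(mp$position_um, mp[[channels[i]]], col = cols[i], lwd = 2)
  legend("topright", legend = channels, col = cols, lwd = 2, bty = "n")
  invisible(x)
}
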