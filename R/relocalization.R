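# Live relocalization quantification: spindle-ROI axial profiles at the
# initial and final timepoints, the final/initial ratio on a normalized
# 0-100% spindle-length grid, and its area under the curve.

#' Axial intensity profile of a rectangular spindle ROI
#'
#' Mean intensity along the ROI's long axis (the spindle axis): at each
#' position along the longer side, the mean over the shorter side.  Raw
#' intensity units are kept -- no internal normalization -- because the
#' downstream final/initial ratio needs commensurate scales.
#'
#' @param frame a `spindle_image`.
#' @param roi integer vector `(row0, col0, row1, col1)`, 1-based inclusive
#'   pixel bounds of the rectangle.
#' @param channel channel role to profile (default `"motor"`).
#' @return An `axial_intensity`: data.frame with `position_um` (0 at the
#'   ROI edge) and `intensity`.
#' @export
spindle_profile_at <- function(frame, roi, channel = "motor") {
  stopifnot(inherits(frame, "spindle_image"))
  if (length(roi) != 4) stopf("roi must be (row0, col0, row1, col1)")
  roi <- as.integer(roi)
  r <- sort(roi[c(1, 3)]); cl <- sort(roi[c(2, 4)])
  nr <- nrow(frame$data); nc <- ncol(frame$data)
  if (r[1] < 1 || r[2] > nr || cl[1] < 1 || cl[2] > nc)
    stopf("roi (%d:%d, %d:%d) lies outside the %d x %d frame",
          r[1], r[2], cl[1], cl[2], nr, nc)
  m <- channel_matrix(frame, channel)[r[1]:r[2], cl[1]:cl[2], drop = FALSE]
  prof <- if (ncol(m) >= nrow(m)) colMeans(m) else rowMeans(m)
  out <- data.frame(position_um = (seq_along(prof) - 1) * frame$pixel_size_um,
                    intensity = as.numeric(prof))
  class(out) <- c("axial_intensity", "data.frame")
  out
}

#' Final/initial fluorescence ratio vs percent spindle length
#'
#' Resamples the initial and final axial profiles of one cell onto a common
#' 0-100% spindle-length grid by linear interpolation and divides pointwise.
#' The denominator is floored at `floor_frac` of the initial profile's mean
#' intensity to prevent ratio blow-ups at the spindle edges; the number of
#' floored grid points is recorded in `floor_hits`.
#'
#' @param initial,final `axial_intensity` profiles of the same cell
#'   (pre-treatment and, conventionally, 12 min post-treatment).
#' @param grid_points number of grid points on `[0, 100]` (default 101).
#' @param cell_id identifier.
#' @param t_initial_s,t_final_s timepoints in seconds relative to treatment
#'   (defaults -90 s and +720 s).
#' @param floor_frac denominator floor as a fraction of the initial
#'   profile's mean.
#' @return A `ratio_profile`: `percent_length`, `ratio` (> 0 everywhere),
#'   `auc` (trapezoidal integral of the ratio over `[0, 100]`), `cell_id`,
#'   timepoints, `floor_hits`.
#' @export
#' @examples
#' p <- data.frame(position_um = 0:50 / 5, intensity = 100 + 0 * (0:50))
#' class(p) <- c("axial_intensity", "data.frame")
#' ratio_profile(p, p)$auc  # identical frames: AUC = 100
ratio_profile <- function(initial, final, grid_points = 101L,
                          cell_id = NA_character_,
                          t_initial_s = -90, t_final_s = 720,
                          floor_frac = 0.01) {
  for (p in list(initial, final)) {
    if (!all(c("position_um", "intensity") %in% names(p)))
      stopf("profiles need columns position_um and intensity")
  }
  if (!is_count(grid_points) || grid_points < 2)
    stopf("grid_points must be >= 2")
  len_i <- max(initial$position_um); len_f <- max(final$position_um)
  if (len_i <= 0 || len_f <= 0) stopf("degenerate profile (zero length)")
  if (max(len_i, len_f) / min(len_i, len_f) > 2)
    stopf("ROI lengths differ by more than 2-fold (%.2f vs %.2f um): not the same spindle?",
          len_i, len_f)
  if (mean(initial$intensity) <= 0 || mean(final$intensity) <= 0)
    stopf("profiles must have positive mean intensity")
  grid <- seq(0, 100, length.out = grid_points)
  res_i <- approx(initial$position_um / len_i * 100, initial$intensity,
                  xout = grid)$y
  res_f <- approx(final$position_um / len_f * 100, final$intensity,
                  xout = grid)$y
  eps <- floor_frac * mean(initial$intensity)
  floored <- res_i < eps
  denom <- pmax(res_i, eps)
  ratio <- res_f / denom
  rp <- structure(list(percent_length = grid, ratio = ratio,
                       cell_id = cell_id,
                       t_initial_s = t_initial_s, t_final_s = t_final_s,
                       floor_hits = sum(floored),
                       auc = trapz(grid, ratio)),
                  class = "ratio_profile")
  if (rp$floor_hits > 0)
    message(sprintf("ratio_profile(%s): denominator floor triggered at %d/%d grid points",
                    cell_id, rp$floor_hits, grid_points))
  rp
}

#' Area under a final/initial ratio curve
#'
#' Trapezoidal integral of the ratio over percent spindle length 0-100,
#' baseline y = 0.  An unchanged cell (ratio identically 1) has AUC 100;
#' redistribution of fluorescence moves the AUC away from 100 in the
#' direction set by the pole-gain vs midzone-loss balance.
#'
#' @param rp a `ratio_profile`.
#' @return The area (numeric).
#' @export
auc <- function(rp) {
  stopifnot(inherits(rp, "ratio_profile"))
  trapz(rp$percent_length, rp$ratio)
}

#' @export
print.ratio_profile <- function(x, ...) {
  cat(sprintf("<ratio_profile> %s%d grid points, t = %+.0f s -> %+.0f s, AUC = %.2f%s\n",
              if (is.na(x$cell_id)) "" else paste0(x$cell_id, ": "),
              length(x$percent_length), x$t_initial_s, x$t_final_s, x$auc,
              if (x$floor_hits > 0)
                sprintf(" (%d floored points)", x$floor_hits) else ""))
  invisible(x)
}

#' @export
plot.ratio_profile <- function(x, ...) {
  plot(x$percent_length, x$ratio, type = "l", lwd = 2,
       xlab = "% spindle length", ylab = "final / initial fluorescence", ...)
  abline(h = 1, lty = 3)
  invisible(x)
}
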