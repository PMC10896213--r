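# Chromosome-alignment metric: pole detection, spindle length, the axial
# DNA/centromere intensity profile, its Gaussian fit and FWHM, and
# background-subtracted spindle expression quantification.

# Greedy peak picking on a smoothed channel: local maxima ranked by
# intensity, kept if >= min_separation_um from every already-kept peak.
# Ties break toward the smallest row, then smallest column.
find_peaks <- function(m, pixel_size_um, min_separation_um,
                       rel_threshold = 0, n_max = Inf) {
  sm <- smooth3x3(m)
  nr <- nrow(sm); nc <- ncol(sm)
  inner_r <- 2:(nr - 1); inner_c <- 2:(nc - 1)
  ctr <- sm[inner_r, inner_c]
  is_max <- ctr >= sm[inner_r - 1, inner_c - 1] & ctr >= sm[inner_r - 1, inner_c] &
    ctr >= sm[inner_r - 1, inner_c + 1] & ctr >= sm[inner_r, inner_c - 1] &
    ctr >= sm[inner_r, inner_c + 1] & ctr >= sm[inner_r + 1, inner_c - 1] &
    ctr >= sm[inner_r + 1, inner_c] & ctr >= sm[inner_r + 1, inner_c + 1]
  thr <- rel_threshold * max(sm)
  cand <- which(is_max & ctr > thr, arr.ind = TRUE)
  if (nrow(cand) == 0) return(cbind(row_um = numeric(0), col_um = numeric(0)))
  cand <- cand + 1L  # back to full-matrix indices
  vals <- sm[cand]
  ord <- order(-vals, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  kept <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(cand))) {
    p <- (cand[i, ] - 1) * pixel_size_um
    if (nrow(kept) == 0 ||
        all(sqrt(rowSums((kept - matrix(p, nrow(kept), 2,
                                        byrow = TRUE))^2)) >=
            min_separation_um)) {
      kept <- rbind(kept, p)
      if (nrow(kept) >= n_max) break
    }
  }
  colnames(kept) <- c("row_um", "col_um")
  rownames(kept) <- NULL
  kept
}

#' Detect spindle poles from the pole channel
#'
#' Finds the `n` strongest local maxima of the 3x3-mean-smoothed pole
#' (gamma-tubulin) channel separated by at least `min_separation_um`; ties
#' break toward the smallest row, then column.  Used to anchor line scans
#' and the pole-to-pole axis when pole coordinates are not supplied.
#'
#' @param image a `spindle_image`.
#' @param n number of poles to return (default 2).
#' @param min_separation_um minimum pairwise separation (default 2 um).
#' @param channel channel role holding the pole marker.
#' @return An `n x 2` matrix of `(row_um, col_um)` positions, strongest
#'   first.
#' @export
detect_poles <- function(image, n = 2L, min_separation_um = 2,
                         channel = "pole") {
  m <- channel_matrix(image, channel)
  pk <- find_peaks(m, image$pixel_size_um, min_separation_um, n_max = n)
  if (nrow(pk) < n)
    stopf("found only %d pole candidate(s); expected %d", nrow(pk), n)
  pk
}

#' Spindle length as pole-to-pole Euclidean distance
#'
#' @param pole_a,pole_b `(row, col)` pole positions in micrometres.
#' @return Length in micrometres.
#' @export
#' @examples
#' measure_spindle_length(c(0, 0), c(3, 4))  # 5
measure_spindle_length <- function(pole_a, pole_b) {
  stopifnot(length(pole_a) == 2, length(pole_b) == 2)
  d <- sqrt(sum((as.numeric(pole_a) - as.numeric(pole_b))^2))
  if (d == 0) stopf("poles coincide: spindle length undefined")
  d
}

#' Axial intensity profile along the pole-to-pole axis
#'
#' Measures the named channel in a boxed region of interest whose width is
#' the spindle length and whose height is `box_height_um`: at each axial
#' step (one pixel pitch) the intensity is the mean over the box height
#' perpendicular to the axis, and the resulting profile is normalized
#' internally to its maximum.  This is the chromosome-distribution input to
#' [fit_gaussian_fwhm()].
#'
#' @param image a `spindle_image`.
#' @param pole_a,pole_b pole positions in micrometres (e.g. from
#'   [detect_poles()]).
#' @param channel channel role to profile (DNA or centromere marker).
#' @param box_height_um box height perpendicular to the axis (default 5 um).
#' @return An `axis_profile`: `positions_um` spanning `[0, spindle length]`,
#'   `intensity` with maximum exactly 1, `spindle_length_um`,
#'   `box_height_um`.
#' @export
axis_profile <- function(image, pole_a, pole_b, channel = "dna",
                         box_height_um = 5) {
  stopifnot(inherits(image, "spindle_image"))
  L <- measure_spindle_length(pole_a, pole_b)
  m <- channel_matrix(image, channel)
  px <- image$pixel_size_um
  u <- (as.numeric(pole_b) - as.numeric(pole_a)) / L
  v <- c(-u[2], u[1])
  s <- seq(0, L, by = px)
  offsets <- seq(-box_height_um / 2, box_height_um / 2, by = px)
  R <- outer(pole_a[1] + s * u[1], offsets * v[1], `+`) / px + 1
  C <- outer(pole_a[2] + s * u[2], offsets * v[2], `+`) / px + 1
  nr <- nrow(m); nc <- ncol(m)
  if (any(R < 1 - 1e-9 | R > nr + 1e-9 | C < 1 - 1e-9 | C > nc + 1e-9))
    stopf("the %g x %.2f um box exceeds the image bounds", box_height_um, L)
  R <- pmin(pmax(R, 1), nr); C <- pmin(pmax(C, 1), nc)
  prof <- rowMeans(matrix(bilinear_sample(m, as.vector(R), as.vector(C)),
                          nrow = length(s)))
  mx <- max(prof)
  if (mx <= 0) stopf("channel '%s' has no positive signal in the box", channel)
  structure(list(positions_um = s, intensity = prof / mx,
                 spindle_length_um = L, box_height_um = box_height_um,
                 channel = channel),
            class = "axis_profile")
}

#' Fit a Gaussian to an axial profile and report the FWHM
#'
#' Least-squares fit of `b + a * exp(-(x - mu)^2 / (2 sigma^2))` to the
#' normalized axial intensity profile, with moment-based initialization
#' (`mu0` = intensity-weighted mean, `sigma0` = weighted sd, `b0` = min,
#' `a0` = max - min) and box bounds `a > 0`,
#' `sigma in (0, spindle length]`, `mu in [0, spindle length]`,
#' `b in [0, max(y)]`.  The chromosome-alignment statistic is the full
#' width at half maximum, `fwhm = 2 sqrt(2 ln 2) sigma`; smaller means a
#' tighter metaphase plate.
#'
#' @param profile an [axis_profile()], or a data.frame/list with
#'   `positions_um` and `intensity`.
#' @return A `gaussian_fit` with `amplitude`, `center`, `sd`, `offset`,
#'   `fwhm`, `rss`, `converged`.  Non-convergence is reported via
#'   `converged = FALSE` (the cell should then be excluded from cohort
#'   summaries), never by silently dropping the cell.
#' @export
#' @examples
#' x <- seq(0, 10, by = 0.1)
#' y <- exp(-(x - 5)^2 / 2)  # sigma = 1
#' fit <- fit_gaussian_fwhm(data.frame(positions_um = x, intensity = y))
#' round(fit$fwhm, 4)  # 2.3548
fit_gaussian_fwhm <- function(profile) {
  x <- profile$positions_um
  y <- profile$intensity
  if (length(x) < 5) stopf("need >= 5 samples to fit a Gaussian")
  if (diff(range(y)) == 0) stopf("flat profile: Gaussian fit undefined")
  L <- if (!is.null(profile$spindle_length_um)) profile$spindle_length_um
  else diff(range(x))
  w <- y - min(y)
  sw <- sum(w)
  mu0 <- if (sw > 0) sum(x * w) / sw else mean(x)
  sigma0 <- if (sw > 0) sqrt(max(sum(w * (x - mu0)^2) / sw, 1e-6))
  else L / 4
  start <- list(a = max(y) - min(y), mu = mu0,
                sigma = min(max(sigma0, 1e-3), L), b = min(y))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ b + a * exp(-(x - mu)^2 / (2 * sigma^2)),
      start = start,
      lower = c(a = 1e-9, mu = 0, sigma = 1e-6, b = 0),
      upper = c(a = Inf, mu = L, sigma = L, b = max(y)),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(amplitude = NA_real_, center = NA_real_,
                          sd = NA_real_, offset = NA_real_, fwhm = NA_real_,
                          rss = NA_real_, converged = FALSE,
                          spindle_length_um = L),
                     class = "gaussian_fit"))
  }
  cf <- coef(fit)
  structure(list(amplitude = unname(cf["a"]), center = unname(cf["mu"]),
                 sd = unname(cf["sigma"]), offset = unname(cf["b"]),
                 fwhm = fwhm_factor * unname(cf["sigma"]),
                 rss = sum(resid(fit)^2), converged = TRUE,
                 spindle_length_um = L),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, digits = 4, ...) {
  if (!x$converged) {
    cat("<gaussian_fit> did not converge (exclude this cell)\n")
    return(invisible(x))
  }
  cat(sprintf("<gaussian_fit> FWHM = %s um (sigma = %s, center = %s, offset = %s, rss = %s)\n",
              format(x$fwhm, digits = digits),
              format(x$sd, digits = digits),
              format(x$center, digits = digits),
              format(x$offset, digits = digits),
              format(x$rss, digits = 3)))
  invisible(x)
}

#' @export
coef.gaussian_fit <- function(object, ...) {
  c(amplitude = object$amplitude, center = object$center, sd = object$sd,
    offset = object$offset)
}

#' @export
predict.gaussian_fit <- function(object, newdata, ...) {
  x <- if (is.list(newdata)) newdata$positions_um else newdata
  object$offset + object$amplitude *
    exp(-(x - object$center)^2 / (2 * object$sd^2))
}

#' @export
plot.axis_profile <- function(x, fit = NULL, ...) {
  plot(x$positions_um, x$intensity, type = "l", lwd = 2,
       xlab = "position along pole-to-pole axis (um)",
       ylab = sprintf("normalized %s intensity", x$channel), ...)
  if (!is.null(fit) && isTRUE(fit$converged)) {
    lines(x$positions_um, predict(fit, x), col = 2, lty = 2, lwd = 2)
    abline(v = fit$center + c(-0.5, 0.5) * fit$fwhm, col = 2, lty = 3)
  }
  invisible(x)
}

#' Background-subtracted, cohort-normalized spindle intensity
#'
#' For each cell the corrected intensity is the mean spindle-ROI signal
#' minus the mean background-ROI signal from the same image; corrected
#' values are then divided by their cohort mean, so the normalized cohort
#' mean is 1 by construction.  Used to verify equal expression across
#' construct cohorts.
#'
#' @param records data.frame with columns `cell_id`, `spindle_mean`,
#'   `background_mean`.
#' @return The data.frame with added `corrected` and `normalized` columns.
#' @export
#' @examples
#' expression_quant(data.frame(cell_id = 1:3,
#'                             spindle_mean = c(110, 120, 130),
#'                             background_mean = 100))$normalized
expression_quant <- function(records) {
  need <- c("cell_id", "spindle_mean", "background_mean")
  if (!all(need %in% names(records)))
    stopf("records must have columns: %s", paste(need, collapse = ", "))
  if (nrow(records) < 1) stopf("need at least one record")
  records$corrected <- records$spindle_mean - records$background_mean
  mc <- mean(records$corrected)
  if (mc <= 0)
    stopf("no signal: cohort mean corrected intensity is not positive")
  records$normalized <- records$corrected / mc
  records
}
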