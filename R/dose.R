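# Dose-response analysis of microtubule-stimulated ATPase inhibition:
# the percent-inhibition transform and the four-parameter logistic
# ("variable slope") fit yielding the IC50.

#' Percent inhibition from control-normalized signals
#'
#' `100 * (pos - sample) / (pos - neg)`, where `pos` is the positive
#' (uninhibited enzyme) control signal and `neg` the negative (no-enzyme)
#' control.  Noisy wells may fall outside `[0, 100]`; values are not
#' clipped, and out-of-range entries are flagged via the `out_of_range`
#' attribute.  The transform is invariant to adding a constant to all three
#' signals and to scaling all three by a common factor.
#'
#' @param sample sample signal(s); vectorized.
#' @param pos,neg control signals.
#' @return Percent inhibition, attribute `out_of_range`.
#' @export
#' @examples
#' percent_inhibition(c(100, 50, 0), pos = 100, neg = 0)  # 0, 50, 100
percent_inhibition <- function(sample, pos, neg) {
  if (!is_num1(pos) || !is_num1(neg)) stopf("pos and neg must be scalars")
  if (pos == neg) stopf("positive and negative control signals coincide")
  out <- 100 * (pos - sample) / (pos - neg)
  structure(out, out_of_range = out < 0 | out > 100)
}

#' Build an inhibition curve from a dose-response well table
#'
#' Converts raw per-well signals into replicate-resolved percent inhibition
#' using the mean positive- and negative-control signals.  Accepts tables
#' from [simulate_dose_response()] (a `role` column marking `pos`/`neg`
#' wells) or explicit control values.
#'
#' @param wells data.frame with `concentration_nM`, `replicate`, `signal`
#'   and optionally `role`.
#' @param pos,neg control signals; defaults are the means of the `pos` /
#'   `neg` rows of `wells`.
#' @return An `inhibition_curve`: data.frame `data` with
#'   `concentration_nM`, `replicate`, `percent_inhibition`,
#'   `out_of_range`; plus `pos_signal`, `neg_signal`.
#' @export
inhibition_curve <- function(wells, pos = NULL, neg = NULL) {
  need <- c("concentration_nM", "replicate", "signal")
  if (!all(need %in% names(wells)))
    stopf("wells must have columns: %s", paste(need, collapse = ", "))
  if (is.null(pos) || is.null(neg)) {
    if (!"role" %in% names(wells))
      stopf("supply pos/neg controls or a 'role' column")
    if (is.null(pos)) pos <- mean(wells$signal[wells$role == "pos"])
    if (is.null(neg)) neg <- mean(wells$signal[wells$role == "neg"])
  }
  samples <- if ("role" %in% names(wells)) wells[wells$role == "sample", ]
  else wells
  if (any(!is.finite(samples$concentration_nM)) ||
      any(samples$concentration_nM <= 0))
    stopf("sample concentrations must be positive and finite")
  pi <- percent_inhibition(samples$signal, pos, neg)
  data <- data.frame(concentration_nM = samples$concentration_nM,
                     replicate = samples$replicate,
                     percent_inhibition = as.numeric(pi),
                     out_of_range = attr(pi, "out_of_range"))
  structure(list(data = data, pos_signal = pos, neg_signal = neg),
            class = "inhibition_curve")
}

#' Fit a four-parameter logistic (variable slope) inhibition curve
#'
#' Least-squares fit of
#' `y(c) = bottom + (top - bottom) / (1 + 10^((log10(ic50) - log10(c)) * hill))`
#' to replicate-resolved percent inhibition, in log10-concentration space
#' (the Prism "variable slope" convention).  Initialization: `top` = max y,
#' `bottom` = min y, `ic50` = concentration where the curve crosses halfway
#' between the plateaus (log-linear interpolation), `hill` = 1.  Bounds:
#' `ic50 > 0`, `hill` in `[0.1, 10]`; top and bottom are unconstrained
#' (fitted, not pinned to 100/0).
#'
#' @param curve an [inhibition_curve()], or a data.frame with
#'   `concentration_nM` and `percent_inhibition`.
#' @param average_replicates fit replicate means instead of pointwise
#'   replicates (default FALSE: replicates enter the loss individually).
#' @return A `fourpl_fit`: `top`, `bottom`, `ic50_nM`, `hill`, `rss`,
#'   `converged`, `shallow` (TRUE when the observed response spans fewer
#'   than 20 percentage points, in which case the IC50 is poorly
#'   determined), `n`.
#' @export
#' @examples
#' d <- simulate_dose_response(dose_spec(ic50 = 8.2, seed = 1))
#' fit_4pl(inhibition_curve(d))
fit_4pl <- function(curve, average_replicates = FALSE) {
  df <- if (inherits(curve, "inhibition_curve")) curve$data else curve
  if (!all(c("concentration_nM", "percent_inhibition") %in% names(df)))
    stopf("need columns concentration_nM and percent_inhibition")
  if (average_replicates) {
    df <- aggregate(percent_inhibition ~ concentration_nM, df, mean)
  }
  conc <- df$concentration_nM
  y <- df$percent_inhibition
  if (length(unique(conc)) < 5)
    stopf("need >= 5 distinct concentrations for a 4PL fit")
  lx <- log10(conc)
  top0 <- max(y); bot0 <- min(y)
  shallow <- (top0 - bot0) < 20
  # Initial IC50: log-linear interpolation to the half-response crossing.
  my <- tapply(y, lx, mean)
  ux <- as.numeric(names(my))
  half <- (top0 + bot0) / 2
  cross <- which(diff(sign(my - half)) != 0)
  my <- unname(my)
  lic0 <- if (length(cross) > 0) {
    i <- cross[1]
    ux[i] + (half - my[i]) / (my[i + 1] - my[i]) * (ux[i + 1] - ux[i])
  } else mean(range(lx))
  lic0 <- unname(lic0)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + 10^((lic50 - lx) * hill)),
      start = list(top = top0, bottom = bot0, lic50 = lic0, hill = 1),
      lower = c(top = -Inf, bottom = -Inf, lic50 = min(lx) - 3, hill = 0.1),
      upper = c(top = Inf, bottom = Inf, lic50 = max(lx) + 3, hill = 10),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(top = NA_real_, bottom = NA_real_,
                          ic50_nM = NA_real_, hill = NA_real_,
                          rss = NA_real_, converged = FALSE,
                          shallow = shallow, n = length(y)),
                     class = "fourpl_fit"))
  }
  cf <- coef(fit)
  structure(list(top = unname(cf["top"]), bottom = unname(cf["bottom"]),
                 ic50_nM = 10^unname(cf["lic50"]), hill = unname(cf["hill"]),
                 rss = sum(resid(fit)^2), converged = TRUE,
                 shallow = shallow, n = length(y)),
            class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, digits = 4, ...) {
  if (!x$converged) {
    cat("<fourpl_fit> did not converge: IC50 not reported\n")
    return(invisible(x))
  }
  cat(sprintf("<fourpl_fit> IC50 = %s nM, hill = %s, top = %s%%, bottom = %s%% (rss = %s, n = %d)%s\n",
              format(x$ic50_nM, digits = digits),
              format(x$hill, digits = digits),
              format(x$top, digits = digits),
              format(x$bottom, digits = digits),
              format(x$rss, digits = 3), x$n,
              if (x$shallow) " [shallow: response spans < 20 points]" else ""))
  invisible(x)
}

#' @export
coef.fourpl_fit <- function(object, ...) {
  c(top = object$top, bottom = object$bottom, ic50_nM = object$ic50_nM,
    hill = object$hill)
}

#' @export
predict.fourpl_fit <- function(object, newdata, ...) {
  conc <- if (is.list(newdata)) newdata$concentration_nM else newdata
  object$bottom + (object$top - object$bottom) /
    (1 + 10^((log10(object$ic50_nM) - log10(conc)) * object$hill))
}

#' @export
plot.fourpl_fit <- function(x, curve = NULL, ...) {
  if (!is.null(curve)) {
    df <- if (inherits(curve, "inhibition_curve")) curve$data else curve
    plot(df$concentration_nM, df$percent_inhibition, log = "x",
         xlab = "concentration (nM)", ylab = "% inhibition", ...)
    cx <- 10^seq(log10(min(df$concentration_nM)),
                 log10(max(df$concentration_nM)), length.out = 200)
  } else {
    cx <- 10^seq(log10(x$ic50_nM) - 3, log10(x$ic50_nM) + 3, length.out = 200)
    plot(cx, predict(x, cx), type = "n", log = "x",
         xlab = "concentration (nM)", ylab = "% inhibition", ...)
  }
  lines(cx, predict(x, cx), col = 2, lwd = 2)
  abline(v = x$ic50_nM, lty = 3, col = 2)
  invisible(x)
}
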