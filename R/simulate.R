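# Table-valued generators: field counts, growth curves, dose-response wells.
# Each returns a plain data.frame with a ground-truth manifest attached as
# the "manifest" attribute (see manifest()).

#' Retrieve the ground-truth manifest of a synthetic artifact
#'
#' @param x an object produced by one of the generators.
#' @return The `ground_truth_manifest`, or `NULL` if none is attached.
#' @export
manifest <- function(x) {
  if (is.list(x) && !is.null(x$manifest)) return(x$manifest)
  attr(x, "manifest", exact = TRUE)
}

#' Sample per-field mitotic/multipolar counts
#'
#' For each field of view: total cells ~ Poisson(`cells_per_field_mean`),
#' mitotic ~ Binomial(total, `p_mitotic`), multipolar ~ Binomial(mitotic,
#' `p_multipolar_given_mitotic`).
#'
#' @param spec a [population_spec()].
#' @return A data.frame with columns `field_id`, `total`, `mitotic`,
#'   `multipolar`, manifest attached.
#' @export
#' @examples
#' head(sample_population_counts(population_spec(p_mitotic = 0.12, seed = 3)))
sample_population_counts <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  df <- with_seed(spec$seed, {
    total <- rpois(spec$n_fields, spec$cells_per_field_mean)
    mitotic <- rbinom(spec$n_fields, total, spec$p_mitotic)
    multipolar <- rbinom(spec$n_fields, mitotic,
                         spec$p_multipolar_given_mitotic)
    data.frame(field_id = seq_len(spec$n_fields), total = total,
               mitotic = mitotic, multipolar = multipolar)
  })
  attr(df, "manifest") <- structure(list(
    kind = "population_counts", spec = spec,
    true_mitotic_index_pct = 100 * spec$p_mitotic,
    true_multipolar_pct = 100 * spec$p_multipolar_given_mitotic
  ), class = "ground_truth_manifest")
  df
}

# Logistic growth closed form; Td = Inf gives a constant (arrested)
# population, K = Inf the pure exponential 2^(t/Td) law.
logistic_counts <- function(t, n0, Td, K) {
  if (is.infinite(Td)) return(rep(n0, length(t)))
  if (is.infinite(K)) return(n0 * 2^(t / Td))
  K / (1 + (K / n0 - 1) * 2^(-t / Td))
}

#' Simulate a kinetic proliferation curve
#'
#' Logistic growth `N(t) = K / (1 + (K/n0 - 1) 2^(-t/Td))` sampled every
#' `sample_interval_h` hours up to `horizon_h`, with multiplicative
#' log-normal (mean 1, cv `count_noise_cv`) counting noise.
#'
#' @param spec a [growth_spec()].
#' @return A data.frame with columns `time_h`, `count`, manifest attached
#'   (includes `true_fold_change`, the noise-free final/initial ratio).
#' @export
simulate_growth_curve <- function(spec) {
  stopifnot(inherits(spec, "growth_spec"))
  t <- seq(0, spec$horizon_h, by = spec$sample_interval_h)
  n <- logistic_counts(t, spec$n0, spec$doubling_time_h,
                       spec$carrying_capacity)
  counts <- if (spec$count_noise_cv > 0) {
    sdlog <- sqrt(log(1 + spec$count_noise_cv^2))
    with_seed(spec$seed,
              n * rlnorm(length(n), meanlog = -sdlog^2 / 2, sdlog = sdlog))
  } else n
  df <- data.frame(time_h = t, count = counts)
  attr(df, "manifest") <- structure(list(
    kind = "growth_curve", spec = spec,
    true_fold_change = n[length(n)] / n[1]
  ), class = "ground_truth_manifest")
  df
}

#' Simulate an ATPase inhibition dose-response table
#'
#' Generates per-well luminescence `signal(c) = bottom +
#' (top - bottom) / (1 + (c/ic50)^hill)` with Gaussian replicate noise, plus
#' positive-control wells (enzyme, no compound: signal `top`) and
#' negative-control wells (no enzyme: signal `bottom`).
#'
#' @param spec a [dose_spec()].
#' @return A data.frame with columns `concentration_nM`, `replicate`,
#'   `signal`, `role` (`"sample"`, `"pos"` or `"neg"`; controls carry
#'   `concentration_nM = NA`), manifest attached.
#' @export
#' @examples
#' d <- simulate_dose_response(dose_spec(ic50 = 8.2, seed = 2))
#' manifest(d)$true_ic50
simulate_dose_response <- function(spec) {
  stopifnot(inherits(spec, "dose_spec"))
  conc <- spec$concentrations
  nrep <- spec$n_replicates
  mu_sample <- spec$bottom + (spec$top - spec$bottom) /
    (1 + (conc / spec$ic50)^spec$hill)
  df <- with_seed(spec$seed, {
    noisy <- function(mu, n) {
      if (spec$replicate_sd > 0) mu + rnorm(n, sd = spec$replicate_sd)
      else rep(mu, length.out = n)
    }
    sample_rows <- data.frame(
      concentration_nM = rep(conc, each = nrep),
      replicate = rep(seq_len(nrep), times = length(conc)),
      signal = as.numeric(vapply(mu_sample, noisy, numeric(nrep), n = nrep)),
      role = "sample")
    ctrl <- function(mu, role) data.frame(
      concentration_nM = NA_real_, replicate = seq_len(nrep),
      signal = noisy(mu, nrep), role = role)
    rbind(sample_rows, ctrl(spec$top, "pos"), ctrl(spec$bottom, "neg"))
  })
  attr(df, "manifest") <- structure(list(
    kind = "dose_response", spec = spec,
    true_ic50 = spec$ic50, true_hill = spec$hill,
    true_top = spec$top, true_bottom = spec$bottom
  ), class = "ground_truth_manifest")
  df
}
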