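# Counting statistics (mitotic index, multipolarity, chi-squared
# comparison, image-based pole counting) and kinetic-proliferation
# normalization.

#' Per-condition field counts
#'
#' Bundles per-field (total, mitotic, multipolar) counts for one condition
#' and validates `0 <= multipolar <= mitotic <= total` in every field.
#' Mitotic classification itself is upstream (manual scoring or simulator
#' truth); this container only pools and summarises.
#'
#' @param condition condition label.
#' @param fields data.frame with columns `total`, `mitotic`, `multipolar`
#'   (e.g. from [sample_population_counts()]).
#' @return A `condition_counts` object with pooled totals.
#' @export
condition_counts <- function(condition, fields) {
  need <- c("total", "mitotic", "multipolar")
  if (!all(need %in% names(fields)))
    stopf("fields must have columns: %s", paste(need, collapse = ", "))
  bad <- fields$multipolar > fields$mitotic | fields$mitotic > fields$total |
    fields$multipolar < 0
  if (any(bad))
    stopf("invalid counts in %d field(s): need 0 <= multipolar <= mitotic <= total",
          sum(bad))
  structure(list(condition = condition, fields = fields,
                 pooled = list(total = sum(fields$total),
                               mitotic = sum(fields$mitotic),
                               multipolar = sum(fields$multipolar))),
            class = "condition_counts")
}

#' @export
print.condition_counts <- function(x, ...) {
  cat(sprintf("<condition_counts> '%s': %d fields, %d cells, %d mitotic (%.2f%%), %d multipolar\n",
              x$condition, nrow(x$fields), x$pooled$total, x$pooled$mitotic,
              100 * x$pooled$mitotic / max(x$pooled$total, 1),
              x$pooled$multipolar))
  invisible(x)
}

#' Mitotic index (% of cells in mitosis)
#'
#' `100 * pooled mitotic / pooled total`; with `per_field = TRUE` the
#' per-field percentages are returned instead (figures typically plot
#' replicate means alongside the pooled value).
#'
#' @param counts a [condition_counts()].
#' @param per_field return per-field percentages instead of the pooled one.
#' @return Percentage (scalar, or vector if `per_field`).
#' @export
#' @examples
#' cc <- condition_counts("ctrl", data.frame(total = c(100, 100),
#'                                           mitotic = c(10, 20),
#'                                           multipolar = 0))
#' mitotic_index(cc)  # 15
mitotic_index <- function(counts, per_field = FALSE) {
  stopifnot(inherits(counts, "condition_counts"))
  if (per_field) {
    if (any(counts$fields$total == 0)) stopf("a field has zero total cells")
    return(100 * counts$fields$mitotic / counts$fields$total)
  }
  if (counts$pooled$total == 0) stopf("pooled total is zero")
  100 * counts$pooled$mitotic / counts$pooled$total
}

#' Multipolar spindle fraction (% of mitotic cells)
#'
#' `100 * pooled multipolar / pooled mitotic`.
#'
#' @inheritParams mitotic_index
#' @return Percentage.
#' @export
multipolar_fraction <- function(counts, per_field = FALSE) {
  stopifnot(inherits(counts, "condition_counts"))
  if (per_field) {
    return(ifelse(counts$fields$mitotic > 0,
                  100 * counts$fields$multipolar / counts$fields$mitotic,
                  NA_real_))
  }
  if (counts$pooled$mitotic == 0) stopf("pooled mitotic count is zero")
  100 * counts$pooled$multipolar / counts$pooled$mitotic
}

#' Chi-squared comparison of pooled counts between conditions
#'
#' Pearson chi-squared on the pooled `k x 2` contingency table of outcome
#' vs rest, without continuity correction (pooled counts are large).  For
#' `outcome = "mitotic"` the denominator is total cells; for
#' `"multipolar"` it is mitotic cells.  The customary use is pairwise
#' against control (`k = 2`, df 1); passing more conditions tests the full
#' table.
#'
#' @param a,b [condition_counts()] objects.
#' @param ... further `condition_counts` for a full-table test.
#' @param outcome `"mitotic"` or `"multipolar"`.
#' @return A `chisq_compare` object: `statistic`, `p.value`, `df`, the
#'   `table` used, `expected`, and `low_expected` (TRUE when any expected
#'   cell is below 1, in which case the asymptotic p-value is unreliable).
#' @export
#' @examples
#' a <- condition_counts("ctrl", data.frame(total = 100, mitotic = 10,
#'                                          multipolar = 0))
#' b <- condition_counts("trt", data.frame(total = 100, mitotic = 30,
#'                                         multipolar = 0))
#' chisq_compare(a, b, outcome = "mitotic")$statistic  # 12.5
chisq_compare <- function(a, b, ..., outcome = c("mitotic", "multipolar")) {
  outcome <- match.arg(outcome)
  conds <- c(list(a, b), list(...))
  stopifnot(all(vapply(conds, inherits, logical(1), "condition_counts")))
  tab <- t(vapply(conds, function(cc) {
    hit <- cc$pooled[[outcome]]
    denom <- if (outcome == "mitotic") cc$pooled$total else cc$pooled$mitotic
    if (denom == 0) stopf("condition '%s' has a zero denominator", cc$condition)
    c(hit, denom - hit)
  }, numeric(2)))
  dimnames(tab) <- list(vapply(conds, `[[`, character(1), "condition"),
                        c(outcome, "other"))
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  structure(list(statistic = unname(ct$statistic),
                 p.value = unname(ct$p.value),
                 df = unname(ct$parameter),
                 table = tab, expected = ct$expected,
                 low_expected = any(ct$expected < 1),
                 outcome = outcome),
            class = "chisq_compare")
}

#' @export
print.chisq_compare <- function(x, ...) {
  cat(sprintf("<chisq_compare> outcome '%s': X-squared = %.4g, df = %d, p = %.3g%s\n",
              x$outcome, x$statistic, x$df, x$p.value,
              if (x$low_expected) " [warning: expected cell < 1]" else ""))
  print(x$table)
  invisible(x)
}

#' Count spindle poles in an image
#'
#' Counts local maxima of the 3x3-mean-smoothed pole channel that exceed
#' `rel_threshold` of the channel's smoothed maximum and are pairwise
#' separated by at least `min_separation_um`, retaining only candidates
#' where the (smoothed) tubulin channel also exceeds its image background
#' (median) -- the two-channel criterion used when scoring multipolarity.
#'
#' @param image a `spindle_image`.
#' @param rel_threshold relative intensity threshold (default 0.3).
#' @param min_separation_um minimum pole separation (default 2 um).
#' @param require_tubulin also require local tubulin signal (default TRUE).
#' @return Integer pole count, with the retained positions as attribute
#'   `poles_um`.
#' @export
pole_count <- function(image, rel_threshold = 0.3, min_separation_um = 2,
                       require_tubulin = TRUE) {
  m <- channel_matrix(image, "pole")
  if (all(m == 0)) stopf("empty image: pole channel is all zero")
  pk <- find_peaks(m, image$pixel_size_um, min_separation_um,
                   rel_threshold = rel_threshold)
  if (require_tubulin && nrow(pk) > 0 && "tubulin" %in% image$channels) {
    tub <- smooth3x3(channel_matrix(image, "tubulin"))
    bg <- median(tub)
    keep <- vapply(seq_len(nrow(pk)), function(i) {
      idx <- round(pk[i, ] / image$pixel_size_um) + 1
      tub[idx[1], idx[2]] > bg
    }, logical(1))
    pk <- pk[keep, , drop = FALSE]
  }
  structure(nrow(pk), poles_um = pk)
}

#' Proliferation metrics from kinetic cell-count curves
#'
#' For every well: counts normalized to the first timepoint, the fold
#' change (last / first count), and the normalized fold change (fold change
#' divided by the reference condition's mean fold change, i.e. "% of
#' control" / 100).  Per-condition mean and sd of the normalized count
#' curves are also returned for plotting.
#'
#' @param growth data.frame with columns `condition`, `well_id`, `time_h`,
#'   `count` (one row per well per timepoint).
#' @param reference_condition label of the control condition used for
#'   normalization (e.g. DMSO or the wild-type rescue).
#' @return A `growth_metrics` object: `wells` (per-well `fold_change`,
#'   `normalized_fold_change`, `percent_of_reference`), `curves`
#'   (per-condition per-timepoint mean and sd of normalized counts), and
#'   `normalized` (the input with a `normalized_count` column).
#' @export
#' @examples
#' g <- rbind(
#'   data.frame(condition = "ctrl", well_id = "c1",
#'              time_h = c(0, 24), count = c(100, 200)),
#'   data.frame(condition = "trt", well_id = "t1",
#'              time_h = c(0, 24), count = c(100, 100)))
#' growth_metrics(g, "ctrl")$wells
growth_metrics <- function(growth, reference_condition) {
  need <- c("condition", "well_id", "time_h", "count")
  if (!all(need %in% names(growth)))
    stopf("growth must have columns: %s", paste(need, collapse = ", "))
  if (!reference_condition %in% growth$condition)
    stopf("reference condition '%s' not present", reference_condition)
  growth <- growth[order(growth$condition, growth$well_id, growth$time_h), ]
  key <- interaction(growth$condition, growth$well_id, drop = TRUE)
  wells <- do.call(rbind, lapply(split(growth, key), function(w) {
    if (is.unsorted(w$time_h, strictly = TRUE))
      stopf("well '%s': times must be strictly increasing", w$well_id[1])
    if (w$count[1] <= 0)
      stopf("well '%s': zero initial count, cannot normalize", w$well_id[1])
    data.frame(condition = w$condition[1], well_id = w$well_id[1],
               fold_change = w$count[nrow(w)] / w$count[1])
  }))
  rownames(wells) <- NULL
  ref_mean <- mean(wells$fold_change[wells$condition == reference_condition])
  wells$normalized_fold_change <- wells$fold_change / ref_mean
  wells$percent_of_reference <- 100 * wells$normalized_fold_change

  first_count <- stats::ave(growth$count, key, FUN = function(v) v[1])
  growth$normalized_count <- growth$count / first_count
  curves <- do.call(rbind, lapply(
    split(growth, list(growth$condition, growth$time_h), drop = TRUE),
    function(g) data.frame(condition = g$condition[1], time_h = g$time_h[1],
                           mean_normalized = mean(g$normalized_count),
                           sd_normalized = if (nrow(g) > 1)
                             sd(g$normalized_count) else 0)))
  curves <- curves[order(curves$condition, curves$time_h), ]
  rownames(curves) <- NULL
  structure(list(wells = wells, curves = curves, normalized = growth,
                 reference_condition = reference_condition),
            class = "growth_metrics")
}

#' @export
print.growth_metrics <- function(x, ...) {
  cat(sprintf("<growth_metrics> %d wells, %d conditions (reference: '%s')\n",
              nrow(x$wells), length(unique(x$wells$condition)),
              x$reference_condition))
  agg <- aggregate(normalized_fold_change ~ condition, x$wells, mean)
  names(agg)[2] <- "mean_normalized_fold_change"
  print(agg, row.names = FALSE)
  invisible(x)
}

#' @importFrom stats aggregate ave
#' @export
plot.growth_metrics <- function(x, ...) {
  conds <- unique(x$curves$condition)
  cols <- seq_along(conds)
  plot(range(x$curves$time_h), range(x$curves$mean_normalized), type = "n",
       xlab = "time (h)", ylab = "normalized cell count", ...)
  for (i in seq_along(conds)) {
    g <- x$curves[x$curves$condition == conds[i], ]
    lines(g$time_h, g$mean_normalized, col = cols[i], lwd = 2)
  }
  legend("topleft", legend = conds, col = cols, lwd = 2, bty = "n")
  invisible(x)
}
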