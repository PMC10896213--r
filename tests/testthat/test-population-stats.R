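# Counting statistics, chi-squared comparisons, image-based pole counting,
# and proliferation normalization.

test_that("condition_counts validates per-field ordering constraints", {
  expect_error(condition_counts("x", data.frame(total = 10, mitotic = 12,
                                                multipolar = 0)),
               "multipolar <= mitotic <= total")
  expect_error(condition_counts("x", data.frame(total = 10, mitotic = 5,
                                                multipolar = 7)),
               "multipolar <= mitotic <= total")
})

test_that("mitotic index pools counts and matches the count-weighted field mean", {
  cc <- condition_counts("c", data.frame(total = c(100, 100),
                                         mitotic = c(10, 20),
                                         multipolar = c(0, 0)))
  expect_equal(mitotic_index(cc), 15)
  single <- condition_counts("s", data.frame(total = 100, mitotic = 5,
                                             multipolar = 0))
  expect_equal(mitotic_index(single), 5)
  # pooling consistency: pooled index = count-weighted mean of field indices
  pf <- mitotic_index(cc, per_field = TRUE)
  w <- cc$fields$total / sum(cc$fields$total)
  expect_equal(sum(pf * w), mitotic_index(cc))
  expect_error(mitotic_index(condition_counts("z", data.frame(
    total = 0, mitotic = 0, multipolar = 0))), "zero")
})

test_that("multipolar fraction is a percentage of mitotic cells", {
  cc <- condition_counts("c", data.frame(total = 50, mitotic = 40,
                                         multipolar = 30))
  expect_equal(multipolar_fraction(cc), 75)
  none <- condition_counts("n", data.frame(total = 50, mitotic = 40,
                                           multipolar = 0))
  expect_equal(multipolar_fraction(none), 0)
})

test_that("a mostly-multipolar simulation reads out above 50%", {
  d <- sample_population_counts(population_spec(
    p_mitotic = 0.3, p_multipolar_given_mitotic = 0.7, seed = 21))
  cc <- condition_counts("CIN-like", d)
  expect_gt(multipolar_fraction(cc), 50)
})

test_that("pooled mitotic index recovers the simulated rate within 3 binomial sd", {
  d <- sample_population_counts(population_spec(
    n_fields = 20, cells_per_field_mean = 100, p_mitotic = 0.12, seed = 8))
  cc <- condition_counts("sim", d)
  se_pct <- 100 * sqrt(0.12 * 0.88 / cc$pooled$total)
  expect_lt(abs(mitotic_index(cc) - 12), 3 * se_pct)
})

test_that("chi-squared matches the hand-computed table and is symmetric", {
  a <- condition_counts("a", data.frame(total = 100, mitotic = 10,
                                        multipolar = 0))
  b <- condition_counts("b", data.frame(total = 100, mitotic = 30,
                                        multipolar = 0))
  cmp <- chisq_compare(a, b, outcome = "mitotic")
  # E = [[20,80],[20,80]]; sum (O-E)^2/E = 12.5
  expect_equal(cmp$statistic, 12.5)
  expect_equal(cmp$df, 1)
  expect_equal(unname(cmp$table), rbind(c(10, 90), c(30, 70)))
  expect_equal(chisq_compare(b, a, outcome = "mitotic")$statistic, 12.5)
  same <- chisq_compare(a, a, outcome = "mitotic")
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
})

test_that("chi-squared flags low expected counts and supports full tables", {
  tiny <- condition_counts("t", data.frame(total = 5, mitotic = 0,
                                           multipolar = 0))
  tiny2 <- condition_counts("u", data.frame(total = 5, mitotic = 1,
                                            multipolar = 0))
  expect_true(chisq_compare(tiny, tiny2, outcome = "mitotic")$low_expected)
  a <- condition_counts("a", data.frame(total = 100, mitotic = 10,
                                        multipolar = 0))
  b <- condition_counts("b", data.frame(total = 100, mitotic = 30,
                                        multipolar = 0))
  c3 <- condition_counts("c", data.frame(total = 100, mitotic = 20,
                                         multipolar = 0))
  full <- chisq_compare(a, b, c3, outcome = "mitotic")
  expect_equal(full$df, 2)
})

test_that("null chi-squared comparisons reject at the nominal 5% rate", {
  rejections <- vapply(1:100, function(i) {
    a <- condition_counts("a", sample_population_counts(
      population_spec(p_mitotic = 0.1, seed = 2 * i)))
    b <- condition_counts("b", sample_population_counts(
      population_spec(p_mitotic = 0.1, seed = 2 * i + 1)))
    chisq_compare(a, b, outcome = "mitotic")$p.value < 0.05
  }, logical(1))
  rate <- mean(rejections)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 100))
})

test_that("pole counting matches the simulated pole number", {
  expect_equal(as.integer(pole_count(base_render(seed = 31)$image)), 2L)
  r3 <- render_spindle_image(spindle_spec(n_poles = 3, noise = "none",
                                          seed = 32))
  expect_equal(as.integer(pole_count(r3$image)), 3L)
  expect_error(pole_count(constant_image(0)), "empty")
})

test_that("pole counting agrees with the manifest in >= 95% of noisy renders", {
  set <- expand.grid(np = c(2, 3, 4), rep = 1:20)
  hits <- vapply(seq_len(nrow(set)), function(i) {
    r <- render_spindle_image(spindle_spec(
      n_poles = set$np[i], noise = "poisson", seed = 7000 + i))
    as.integer(pole_count(r$image)) == r$manifest$n_poles
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("growth metrics normalize wells to the reference condition mean", {
  g <- rbind(
    data.frame(condition = "ref", well_id = "r1", time_h = c(0, 120),
               count = c(100, 400)),
    data.frame(condition = "trt", well_id = "t1", time_h = c(0, 120),
               count = c(100, 800)))
  gm <- growth_metrics(g, "ref")
  w <- gm$wells
  expect_equal(w$fold_change[w$condition == "trt"], 8)
  expect_equal(w$normalized_fold_change[w$condition == "trt"], 2)
  expect_equal(mean(w$normalized_fold_change[w$condition == "ref"]), 1)
  expect_error(growth_metrics(rbind(g, data.frame(
    condition = "bad", well_id = "b1", time_h = c(0, 1),
    count = c(0, 10))), "ref"), "initial")
})

test_that("arrest vs exponential growth gives the closed-form 1/32 fold change", {
  mk_well <- function(cond, well, spec) {
    d <- simulate_growth_curve(spec)
    data.frame(condition = cond, well_id = well, time_h = d$time_h,
               count = d$count)
  }
  g <- rbind(
    mk_well("control", "c1", growth_spec(doubling_time_h = 24,
                                         horizon_h = 120,
                                         count_noise_cv = 0)),
    mk_well("arrested", "a1", growth_spec(doubling_time_h = Inf,
                                          horizon_h = 120,
                                          count_noise_cv = 0)))
  gm <- growth_metrics(g, "control")
  w <- gm$wells
  expect_identical(w$normalized_fold_change[w$condition == "arrested"],
                   1 / 32)
  expect_identical(w$normalized_fold_change[w$condition == "control"], 1)
})

test_that("growth metrics are invariant to rescaling a well's counts", {
  g <- rbind(
    data.frame(condition = "ref", well_id = "r1", time_h = c(0, 48, 120),
               count = c(100, 240, 400)),
    data.frame(condition = "trt", well_id = "t1", time_h = c(0, 48, 120),
               count = c(50, 120, 200)))
  gm1 <- growth_metrics(g, "ref")
  g$count[g$well_id == "t1"] <- g$count[g$well_id == "t1"] * 13
  gm2 <- growth_metrics(g, "ref")
  expect_equal(gm1$wells$fold_change, gm2$wells$fold_change)
  expect_equal(gm1$curves, gm2$curves)
})

test_that("slower doubling with concentration yields non-increasing final counts", {
  doses <- c(0, 10, 100, 1000)
  td <- 24 * c(1, 1.3, 2.5, 8)     # doubling slows with concentration
  g <- do.call(rbind, lapply(seq_along(doses), function(i) {
    d <- simulate_growth_curve(growth_spec(doubling_time_h = td[i],
                                           horizon_h = 96,
                                           count_noise_cv = 0))
    data.frame(condition = as.character(doses[i]), well_id = paste0("w", i),
               time_h = d$time_h, count = d$count)
  }))
  gm <- growth_metrics(g, "0")
  w <- gm$wells[match(as.character(doses), gm$wells$condition), ]
  expect_true(all(diff(w$normalized_fold_change) <= 0))
})
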