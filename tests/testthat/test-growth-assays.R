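make_plate <- function(od, ctrl_od, epsilon = 0.001) {
  tibble::tibble(
    plate = "P1", column = 1L, time_h = 0,
    species = c("A", NA), treatment = c("ancestral", NA),
    replicate = c(1L, NA), substrate = "unused",
    od600 = c(od, ctrl_od), is_control = c(FALSE, TRUE))
}

test_that("blank correction subtracts matched controls and floors the result", {
  out <- blank_correct(make_plate(0.30, 0.05))
  expect_equal(out$od_corrected, 0.25)
  out2 <- blank_correct(make_plate(0.04, 0.05), epsilon = 0.001)
  expect_equal(out2$od_corrected, 0.001)

  # missing control errors with the offending location
  bad <- make_plate(0.3, 0.05)
  bad$column[2] <- 2L
  expect_error(blank_correct(bad), "no sterile control.*col 1")

  # synthetic plate: corrected values recover the generator truth
  cfg <- tiny_config(noise_od = 0)
  rows <- simulate_growth_curve(cfg, "A", "ancestral", 1,
                                times = c(0, 24, 48), n0 = 1e6)
  corr <- blank_correct(rows)
  n_true <- 1e6 * exp(cfg$r["A"] * log(2) * c(0, 1, 2)) /
    (1 + 1e6 * (exp(cfg$r["A"] * log(2) * c(0, 1, 2)) - 1) / cfg$K["A"])
  od_true <- (log10(n_true) - cfg$cal_intercepts["A"]) / cfg$cal_slope
  expect_equal(corr$od_corrected, unname(od_true), tolerance = 1e-10)
})

test_that("calibration fit recovers a common slope with species intercepts", {
  # noiseless: exact recovery
  df <- tidyr::expand_grid(species = c("A", "B"), od600 = c(0.1, 0.4, 0.9))
  df$colonies_per_ml <- 10^(ifelse(df$species == "A", 5, 6) + 3 * df$od600)
  fit <- fit_od_calibration(df)
  expect_equal(fit$slope, 3, tolerance = 1e-9)
  expect_equal(unname(fit$intercepts[c("A", "B")]), c(5, 6), tolerance = 1e-9)
  expect_true(is.finite(fit$fit_stats$f) && fit$fit_stats$r_squared > 0.99)

  # constant OD within all species is rank deficient
  bad <- df
  bad$od600 <- 0.5
  expect_error(fit_od_calibration(bad), "distinct OD")
})

test_that("OD converts to log2 density through the species intercept", {
  df <- tidyr::expand_grid(species = c("A", "B"), od600 = c(0.1, 0.5))
  df$colonies_per_ml <- 10^(ifelse(df$species == "A", 5, 6) + 3 * df$od600)
  fit <- fit_od_calibration(df)
  expect_equal(unname(od_to_log_density(fit, 0, "A")), 5 / log10(2),
               tolerance = 1e-9)
  expect_equal(unname(od_to_log_density(fit, 0.3, "B") -
                        od_to_log_density(fit, 0.3, "A")),
               1 / log10(2), tolerance = 1e-9)
  expect_error(od_to_log_density(fit, 0.3, "Z"), "not in calibration")

  # round trip with the generator's inverse calibration
  cfg <- tiny_config(noise_od = 0)
  rows <- blank_correct(simulate_growth_curve(cfg, "A", "ancestral", 1,
                                              times = c(0, 48), n0 = 1e6))
  cal <- truth_calibration(cfg)
  log2n <- od_to_log_density(cal, rows$od_corrected, rows$species)
  expect_equal(unname(log2n[1]), log2(1e6), tolerance = 1e-6)
})

test_that("V_MAX is the OLS slope of log2 density over the first 48 h", {
  curve <- tibble::tibble(time_h = c(0, 24, 48), log2_density = c(10, 11, 12))
  expect_equal(estimate_vmax(curve)$vmax, 1.0, tolerance = 1e-12)

  curve2 <- tibble::tibble(time_h = c(0, 24, 48), log2_density = c(10, 12, 13))
  est2 <- estimate_vmax(curve2)
  expect_equal(est2$vmax, 1.5, tolerance = 1e-12)

  # se agrees with lm on the same window
  fit <- lm(log2_density ~ I(time_h / 24), data = curve2)
  expect_equal(est2$se, summary(fit)$coefficients[2, 2], tolerance = 1e-9)

  # invariant to adding a constant to all log densities
  curve3 <- curve2
  curve3$log2_density <- curve3$log2_density + 7.3
  expect_equal(estimate_vmax(curve3)$vmax, est2$vmax, tolerance = 1e-12)

  # readings beyond the window are ignored
  curve4 <- dplyr::bind_rows(curve2,
                             tibble::tibble(time_h = 96, log2_density = 13.1))
  expect_equal(estimate_vmax(curve4)$vmax, 1.5, tolerance = 1e-12)
  expect_equal(estimate_vmax(curve4)$n_points, 3)

  expect_error(estimate_vmax(tibble::tibble(time_h = 60, log2_density = 1)),
               "fewer than 2")

  # noiseless simulated exponential returns the generating rate
  cfg <- tiny_config(r = c(2, 2), K = c(1e18, 1e18), noise_od = 0)
  rows <- blank_correct(simulate_growth_curve(cfg, "A", "ancestral", 1,
                                              times = seq(0, 96, 24),
                                              n0 = 1e6))
  curve5 <- calibrate_growth(rows, truth_calibration(cfg))
  expect_equal(estimate_vmax(curve5)$vmax, 2.0, tolerance = 1e-6)
})

test_that("carrying capacity is the calibrated density nearest 96 h", {
  curve <- tibble::tibble(time_h = seq(0, 96, 24),
                          log2_density = c(20, 22, 24, 26, 28))
  expect_equal(carrying_capacity(curve), 28 * log10(2), tolerance = 1e-12)

  curve2 <- tibble::tibble(time_h = c(0, 95), log2_density = c(20, 27))
  expect_equal(carrying_capacity(curve2, tolerance_h = 2), 27 * log10(2))
  expect_error(carrying_capacity(tibble::tibble(time_h = c(0, 48),
                                                log2_density = c(1, 2))),
               "no reading")

  # logistic curve reaching K: value near log10 K
  cfg <- tiny_config(r = c(3.5, 3.5), K = c(1e8, 1e8), noise_od = 0)
  rows <- blank_correct(simulate_growth_curve(cfg, "A", "ancestral", 1,
                                              times = seq(0, 96, 24),
                                              n0 = 1e6))
  curve3 <- calibrate_growth(rows, truth_calibration(cfg))
  expect_equal(carrying_capacity(curve3), 8, tolerance = 0.01)
})

test_that("treatment contrasts give exchangeable-null p-values", {
  expect_equal(treatment_contrast(c(1, 2, 3), c(1, 2, 3), B = 99, seed = 1)$p, 1)
  expect_equal(treatment_contrast(c(1, 2, 3), c(1, 2, 3), B = 99, seed = 1)$diff, 0)

  # shifted groups: exact p matches the exhaustive assignment oracle
  ct <- treatment_contrast(c(11, 12, 13), c(1, 2, 3), exact = TRUE)
  expect_equal(ct$p, oracle_exact_diff_p(c(11, 12, 13), c(1, 2, 3)))
  expect_equal(ct$p, 2 / 20) # only the two extreme assignments tie
  expect_equal(ct$diff, 10)

  # Monte Carlo p bounded below by 1/(B+1)
  ct2 <- treatment_contrast(c(11, 12, 13), c(1, 2, 3), B = 199, seed = 5)
  expect_gte(ct2$p, 1 / 200)
  expect_lte(ct2$p, 1)
  expect_error(treatment_contrast(1, c(1, 2)), ">= 2")
})
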