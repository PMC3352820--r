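#' Subtract sterile-medium blanks from plate OD readings
#'
#' Every measurement well is matched to the sterile-control well(s) on the
#' same plate, column and reading time; the control OD (mean, if several)
#' is subtracted and the result floored at `epsilon` so that downstream
#' log-scale calibration is defined.
#'
#' @param plate_rows Assay tibble with columns `plate`, `column`,
#'   `time_h`, `od600`, `is_control` (plus any metadata).
#' @param epsilon Positive floor applied after subtraction (OD units).
#' @return The measurement rows (controls dropped) with an added
#'   `od_corrected` column.
#' @export
blank_correct <- function(plate_rows, epsilon = 0.001) {
  assert_that(epsilon > 0, "epsilon must be positive")
  need <- c("plate", "column", "time_h", "od600", "is_control")
  assert_that(all(need %in% names(plate_rows)),
              paste("missing columns:",
                    paste(setdiff(need, names(plate_rows)), collapse = ", ")))
  ctrl <- plate_rows |>
    dplyr::filter(.data$is_control) |>
    dplyr::group_by(.data$plate, .data$column, .data$time_h) |>
    dplyr::summarise(od_blank = mean(.data$od600), .groups = "drop")
  meas <- dplyr::filter(plate_rows, !.data$is_control)
  out <- dplyr::left_join(meas, ctrl, by = c("plate", "column", "time_h"))
  if (anyNA(out$od_blank)) {
    bad <- out |>
      dplyr::filter(is.na(.data$od_blank)) |>
      dplyr::distinct(.data$plate, .data$column, .data$time_h)
    stop("no sterile control for: ",
         paste(sprintf("(%s, col %s, %g h)", bad$plate, bad$column, bad$time_h),
               collapse = "; "), call. = FALSE)
  }
  out |>
    dplyr::mutate(od_corrected = pmax(.data$od600 - .data$od_blank, epsilon)) |>
    dplyr::select(-"od_blank")
}

#' Fit the OD600-to-colony-count calibration model
#'
#' Least-squares fit of `log10(colonies/ml) ~ species + OD600`: one
#' intercept per species, one shared slope — the model structure retained
#' in the experiment's calibration (different intercepts per species, same
#' slopes).
#'
#' @param calibration_rows Tibble with columns `species`, `od600`,
#'   `colonies_per_ml`.
#' @return Object of class `calibration_model` with elements `slope`,
#'   `intercepts` (named, log10 cells/ml at OD 0), `fit_stats`
#'   (`f`, `df1`, `df2`, `r_squared`), and the underlying `lm` fit.
#' @export
fit_od_calibration <- function(calibration_rows) {
  need <- c("species", "od600", "colonies_per_ml")
  assert_that(all(need %in% names(calibration_rows)),
              paste("missing columns:",
                    paste(setdiff(need, names(calibration_rows)), collapse = ", ")))
  df <- calibration_rows
  assert_that(all(df$colonies_per_ml > 0), "colony counts must be positive")
  n_od <- tapply(df$od600, df$species, function(x) length(unique(x)))
  assert_that(all(n_od >= 2),
              "each species needs >= 2 distinct OD values")
  df$log10_count <- log10(df$colonies_per_ml)
  df$species <- factor(df$species)
  fit <- lm(log10_count ~ 0 + species + od600, data = df)
  co <- coef(fit)
  assert_that(all(is.finite(co)), "calibration fit is rank-deficient")
  slope <- co[["od600"]]
  intercepts <- co[grep("^species", names(co))]
  names(intercepts) <- sub("^species", "", names(intercepts))
  # Overall F and r^2 from the usual intercept parameterisation
  fit1 <- lm(log10_count ~ species + od600, data = df)
  sm <- suppressWarnings(summary(fit1)) # noiseless fits are legitimate here
  structure(list(slope = slope, intercepts = intercepts,
                 fit_stats = list(f = unname(sm$fstatistic["value"]),
                                  df1 = unname(sm$fstatistic["numdf"]),
                                  df2 = unname(sm$fstatistic["dendf"]),
                                  r_squared = sm$r.squared),
                 fit = fit),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("<calibration_model> log10(cells/ml) = intercept[species] +",
      sprintf("%.4g * OD600\n", x$slope))
  cat("  intercepts:", paste(sprintf("%s=%.3g", names(x$intercepts),
                                     x$intercepts), collapse = ", "), "\n")
  cat(sprintf("  F(%g, %g) = %.3g, r^2 = %.3g\n", x$fit_stats$df1,
              x$fit_stats$df2, x$fit_stats$f, x$fit_stats$r_squared))
  invisible(x)
}

#' Convert blank-corrected OD600 to log2 cell density
#'
#' @param model A [fit_od_calibration()] model.
#' @param od Numeric OD600 value(s).
#' @param species Species label(s), recycled against `od`.
#' @return log2 cells/ml.
#' @export
od_to_log_density <- function(model, od, species) {
  stopifnot(inherits(model, "calibration_model"))
  unknown <- setdiff(unique(species), names(model$intercepts))
  assert_that(length(unknown) == 0,
              paste("species not in calibration model:",
                    paste(unknown, collapse = ", ")))
  (model$intercepts[as.character(species)] + model$slope * od) / log10(2)
}

#' Attach calibrated log2 densities to blank-corrected assay rows
#'
#' @param corrected_rows Output of [blank_correct()].
#' @param model A [fit_od_calibration()] model.
#' @return `corrected_rows` with a `log2_density` column.
#' @export
calibrate_growth <- function(corrected_rows, model) {
  corrected_rows |>
    dplyr::mutate(log2_density = od_to_log_density(model, .data$od_corrected,
                                                   .data$species))
}

# Closed-form OLS slope/se of y on x (time in days); se = 0 when n = 2.
ols_slope <- function(x, y) {
  n <- length(x)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  slope <- sum(xc * (y - mean(y))) / sxx
  se <- if (n > 2) {
    res <- y - mean(y) - slope * xc
    sqrt(sum(res^2) / (n - 2) / sxx)
  } else 0
  list(slope = slope, se = se, n = n)
}

#' Estimate the maximum growth rate V_MAX from a growth curve
#'
#' V_MAX is the ordinary least-squares slope of log2 cell density against
#' time (in days) over all readings within the first `window_h` hours —
#' the rate of change in density from low densities, in doublings/day.
#'
#' @param curve Tibble with columns `time_h` and `log2_density` (one
#'   assay well).
#' @param window_h Window over which the slope is taken (default 48 h).
#' @return List of class `vmax_estimate`: `vmax` (doublings/day), `se`,
#'   `n_points`, `window_h`.
#' @export
estimate_vmax <- function(curve, window_h = 48) {
  assert_that(window_h > 0, "window_h must be positive")
  assert_that(all(c("time_h", "log2_density") %in% names(curve)),
              "curve needs time_h and log2_density columns")
  sel <- curve$time_h <= window_h
  assert_that(sum(sel) >= 2,
              sprintf("fewer than 2 readings within %g h", window_h))
  fit <- ols_slope(curve$time_h[sel] / 24, curve$log2_density[sel])
  structure(list(vmax = fit$slope, se = fit$se, n_points = fit$n,
                 window_h = window_h),
            class = "vmax_estimate")
}

#' V_MAX estimates for every isolate x substrate in a calibrated table
#'
#' @param calibrated_rows Output of [calibrate_growth()].
#' @param window_h Passed to [estimate_vmax()].
#' @return Tidy tibble, one row per species x treatment x replicate x
#'   substrate, with `vmax`, `se`, `n_points`.
#' @export
vmax_table <- function(calibrated_rows, window_h = 48) {
  calibrated_rows |>
    dplyr::group_by(.data$species, .data$treatment, .data$replicate,
                    .data$substrate) |>
    dplyr::group_modify(function(d, key) {
      est <- estimate_vmax(d, window_h = window_h)
      tibble::tibble(vmax = est$vmax, se = est$se, n_points = est$n_points)
    }) |>
    dplyr::ungroup()
}

#' Carrying capacity as the calibrated density at 96 h
#'
#' @param curve Tibble with `time_h` and `log2_density`.
#' @param at_h Target time (default 96 h, density after 4 days).
#' @param tolerance_h Maximum distance of the reading used from `at_h`.
#' @return log10 cells/ml at the reading closest to `at_h`.
#' @export
carrying_capacity <- function(curve, at_h = 96, tolerance_h = 4) {
  gap <- abs(curve$time_h - at_h)
  assert_that(any(gap <= tolerance_h),
              sprintf("no reading within %g h of %g h", tolerance_h, at_h))
  i <- which.min(gap)
  unname(curve$log2_density[i] * log10(2))
}

#' Permutation contrast between two groups of V_MAX estimates
#'
#' Difference and ratio of group means with a two-sided permutation
#' p-value (see [perm_diff_test()]); the package's substitute for the
#' original mixed-model/Tukey contrasts.
#'
#' @param vmax_a,vmax_b Numeric vectors of V_MAX estimates (>= 2 each).
#' @param B Number of permutations.
#' @param seed Integer seed.
#' @param exact Enumerate all group assignments.
#' @return Tibble with `diff` (mean a - mean b), `ratio`, `p`, `n_a`,
#'   `n_b`, `B`.
#' @export
treatment_contrast <- function(vmax_a, vmax_b, B = 10000, seed = NULL,
                               exact = FALSE) {
  assert_that(length(vmax_a) >= 2 && length(vmax_b) >= 2,
              "need >= 2 estimates per group")
  pt <- perm_diff_test(vmax_a, vmax_b, B = B, seed = seed, exact = exact)
  tibble::tibble(diff = pt$observed,
                 ratio = if (mean(vmax_b) != 0) mean(vmax_a) / mean(vmax_b) else NA_real_,
                 p = pt$p, n_a = length(vmax_a), n_b = length(vmax_b),
                 B = pt$B)
}
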