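#' Normalise indicator-gel absorbances against blank wells
#'
#' Each well's OD570 trajectory ratio (end / start) is divided by the mean
#' ratio of the blank wells on the plate, so blanks define the
#' zero-respiration baseline `Ai = 1` and respiring wells fall below it
#' (respired CO2 acidifies the cresol-red gel and lowers its absorbance).
#'
#' @param assay_rows Tibble with columns `od570_t0`, `od570_t_end`,
#'   `blank` (at least one blank well required).
#' @return `assay_rows` with an added normalised-absorbance column `ai`.
#' @export
normalize_indicator <- function(assay_rows) {
  need <- c("od570_t0", "od570_t_end", "blank")
  assert_that(all(need %in% names(assay_rows)),
              paste("missing columns:",
                    paste(setdiff(need, names(assay_rows)), collapse = ", ")))
  assert_that(all(assay_rows$od570_t0 > 0), "OD570 readings must be positive")
  assert_that(any(assay_rows$blank), "at least one blank well is required")
  ratio <- assay_rows$od570_t_end / assay_rows$od570_t0
  blank_ratio <- mean(ratio[assay_rows$blank])
  dplyr::mutate(assay_rows, ai = ratio / blank_ratio)
}

#' Convert normalised indicator absorbance to percent CO2
#'
#' Indicator calibration curve `%CO2 = A + B / (1 + D * Ai)`; the
#' constants come from the colorimetric assay's calibration and are
#' configuration, not package truth.
#'
#' @param ai Normalised absorbance(s) from [normalize_indicator()].
#' @param calibration Named vector `c(A, B, D)`.
#' @return Percent CO2 (same length as `ai`).
#' @export
pct_co2 <- function(ai, calibration = c(A = -0.2265, B = -1.606, D = -6.771)) {
  A <- calibration[["A"]]; B <- calibration[["B"]]; D <- calibration[["D"]]
  den <- 1 + D * ai
  assert_that(all(abs(den) > 1e-12), "singular indicator curve: 1 + D*Ai = 0")
  A + B / den
}

#' CO2 respiration rate per ml of culture medium
#'
#' Converts (baseline-subtracted) percent CO2 in the well headspace to a
#' mass rate via the ideal gas law:
#' `ug CO2 = pct/100 * headspace_ml * (44 g/mol / 22.4 l/mol) *
#' 273/(273 + T) * 1000`, then divides by medium volume and incubation
#' time. Negative inputs (plate noise below baseline) are clipped to zero
#' and flagged.
#'
#' @param pct Net percent CO2 (baseline already subtracted).
#' @param headspace_ml Well headspace volume, ml.
#' @param medium_ml Culture medium volume, ml.
#' @param incubation_h Incubation time, hours.
#' @param temperature_c Assay temperature, deg C (default 25, the
#'   incubation temperature).
#' @return Tibble with `rate` (ug CO2 / ml medium / h) and `clipped`.
#' @export
co2_rate <- function(pct, headspace_ml = 1, medium_ml = 1, incubation_h = 6,
                     temperature_c = 25) {
  assert_that(incubation_h > 0, "incubation_h must be positive")
  assert_that(headspace_ml > 0 && medium_ml > 0, "volumes must be positive")
  clipped <- pct < 0
  pct_use <- pmax(pct, 0)
  ug <- pct_use / 100 * headspace_ml * (44 / 22.4) *
    (273 / (273 + temperature_c)) * 1000
  tibble::tibble(rate = ug / medium_ml / incubation_h, clipped = clipped)
}

#' Per-community respiration rates from an indicator plate
#'
#' Full plate reduction: normalise against blanks, convert to percent CO2,
#' subtract the blank (zero-respiration) baseline, convert to rates, and
#' summarise per community.
#'
#' @param assay_rows Plate tibble with `community_id`, `od570_t0`,
#'   `od570_t_end`, `blank` (and optionally `group`).
#' @param calibration Indicator-curve constants, see [pct_co2()].
#' @param headspace_ml,medium_ml,incubation_h,temperature_c Assay
#'   geometry, see [co2_rate()].
#' @return List with `wells` (per-well net pct and rate) and `communities`
#'   (per-community `mean_rate`, `se`, `n`).
#' @export
respiration_rates <- function(assay_rows,
                              calibration = c(A = -0.2265, B = -1.606,
                                              D = -6.771),
                              headspace_ml = 1, medium_ml = 1,
                              incubation_h = 6, temperature_c = 25) {
  norm <- normalize_indicator(assay_rows)
  baseline <- pct_co2(1, calibration)
  wells <- norm |>
    dplyr::filter(!.data$blank) |>
    dplyr::mutate(pct = pct_co2(.data$ai, calibration),
                  pct_net = .data$pct - baseline)
  rates <- co2_rate(wells$pct_net, headspace_ml, medium_ml, incubation_h,
                    temperature_c)
  wells$rate <- rates$rate
  wells$clipped <- rates$clipped
  group_cols <- intersect(c("community_id", "group"), names(wells))
  communities <- wells |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::summarise(mean_rate = mean(.data$rate),
                     se = if (dplyr::n() > 1) se_mean(.data$rate) else 0,
                     n = dplyr::n(), .groups = "drop")
  list(wells = wells, communities = communities)
}

#' Permutation contrast of respiration rates between assembly groups
#'
#' Compares communities reassembled from isolates with different
#' evolutionary histories (e.g. monoculture- vs polyculture-evolved) by a
#' two-sided permutation test on the difference of mean CO2 rates.
#'
#' @param rates_a,rates_b Numeric vectors of per-community rates
#'   (>= 2 each).
#' @param B,seed,exact Passed to [perm_diff_test()].
#' @return Tibble with `diff` (mean a - mean b), `p`, `n_a`, `n_b`, `B`.
#' @export
compare_assemblies <- function(rates_a, rates_b, B = 10000, seed = NULL,
                               exact = FALSE) {
  assert_that(length(rates_a) >= 2 && length(rates_b) >= 2,
              "need >= 2 replicates per group")
  pt <- perm_diff_test(rates_a, rates_b, B = B, seed = seed, exact = exact)
  tibble::tibble(diff = pt$observed, p = pt$p, n_a = length(rates_a),
                 n_b = length(rates_b), B = pt$B)
}
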