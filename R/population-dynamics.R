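validate_transfer_log <- function(log) {
  need <- c("culture_id", "transfer", "density_per_ml", "dilution",
            "volume_ml")
  assert_that(all(need %in% names(log)),
              paste("transfer log missing columns:",
                    paste(setdiff(need, names(log)), collapse = ", ")))
  assert_that(all(log$density_per_ml > 0), "densities must be positive")
  assert_that(all(log$dilution > 1), "dilution factors must exceed 1")
  assert_that(all(log$volume_ml > 0), "volumes must be positive")
  by_culture <- split(log$transfer, log$culture_id)
  ok <- vapply(by_culture, function(t) {
    identical(as.integer(sort(t)), seq_along(t))
  }, logical(1))
  assert_that(all(ok), "transfer indices must be consecutive from 1")
  invisible(log)
}

#' Generations elapsed per serial transfer
#'
#' Each growth cycle starts from the previous culture diluted
#' `dilution`-fold, so the generations in cycle t are
#' `g_t = log2(N_pre(t) / (N_pre(t-1) / dilution))`. For the first cycle
#' the pre-experiment density is taken equal to the first recorded
#' pre-transfer density (steady-state convention), giving
#' `g_1 = log2(dilution)`; a culture held at constant density therefore
#' accumulates `n_transfers * log2(dilution)` generations. Apparent
#' declines below dilution replacement (negative g) are reported as 0 and
#' flagged.
#'
#' @param log Transfer-log tibble with columns `culture_id`, `transfer`,
#'   `density_per_ml`, `dilution`, `volume_ml`.
#' @return List with `per_transfer` (tibble `culture_id`, `transfer`,
#'   `generations`, `clipped`) and `total` (tibble `culture_id`,
#'   `total_generations`).
#' @export
generations <- function(log) {
  validate_transfer_log(log)
  per <- log |>
    dplyr::arrange(.data$culture_id, .data$transfer) |>
    dplyr::group_by(.data$culture_id) |>
    dplyr::mutate(
      n_prev = dplyr::lag(.data$density_per_ml,
                          default = dplyr::first(.data$density_per_ml)),
      g_raw = log2(.data$density_per_ml / (.data$n_prev / .data$dilution)),
      clipped = .data$g_raw < 0,
      generations = pmax(.data$g_raw, 0)) |>
    dplyr::ungroup() |>
    dplyr::select("culture_id", "transfer", "generations", "clipped")
  total <- per |>
    dplyr::group_by(.data$culture_id) |>
    dplyr::summarise(total_generations = sum(.data$generations),
                     .groups = "drop")
  list(per_transfer = per, total = total)
}

#' Effective population size of a serially transferred culture
#'
#' Uses the classic serial-transfer approximation `Ne = N0 * g`, where
#' `N0` is the bottleneck census (mean post-dilution cell number,
#' density / dilution x volume) and `g` the mean generations per
#' transfer. The `"harmonic"` alternative replaces the arithmetic mean
#' bottleneck census by the harmonic mean of the per-transfer `N0_t * g_t`
#' products. The convention used is recorded in the output.
#'
#' @param log Transfer-log tibble (see [generations()]).
#' @param method `"bottleneck_x_generations"` (default) or `"harmonic"`.
#' @return Tibble with one row per culture: `culture_id`, `n_transfers`,
#'   `total_generations`, `mean_generations`, `bottleneck_cells`, `ne`,
#'   `method`.
#' @export
effective_size <- function(log, method = c("bottleneck_x_generations",
                                           "harmonic")) {
  method <- match.arg(method)
  validate_transfer_log(log)
  gen <- generations(log)
  joined <- log |>
    dplyr::mutate(n0_cells = .data$density_per_ml / .data$dilution *
                    .data$volume_ml) |>
    dplyr::left_join(gen$per_transfer, by = c("culture_id", "transfer"))
  joined |>
    dplyr::group_by(.data$culture_id) |>
    dplyr::summarise(
      n_transfers = dplyr::n(),
      total_generations = sum(.data$generations),
      mean_generations = mean(.data$generations),
      bottleneck_cells = mean(.data$n0_cells),
      ne = if (method == "bottleneck_x_generations") {
        mean(.data$n0_cells) * mean(.data$generations)
      } else {
        1 / mean(1 / (.data$n0_cells * pmax(.data$generations, 1e-12)))
      },
      .groups = "drop") |>
    dplyr::mutate(method = method)
}
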