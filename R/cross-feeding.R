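#' Medium-composition deltas for the cross-feeding analysis
#'
#' `delta_01` is the per-compound change after growth of the first
#' species (filtrate 1 minus base medium); `delta_12` is the change after
#' a second species grew on that filtrate (filtrate 2 minus filtrate 1).
#' Positive values indicate production, negative values consumption, and
#' the two deltas telescope: `delta_01 + delta_12 = filtrate2 - base`.
#'
#' @param filtrate1,filtrate2,base Named compound vectors on a shared
#'   peak axis.
#' @return Named delta vector.
#' @export
delta_01 <- function(filtrate1, base) net_change(filtrate1, base)

#' @rdname delta_01
#' @export
delta_12 <- function(filtrate2, filtrate1) net_change(filtrate2, filtrate1)

# Long table of delta_01/delta_12 per (first, second, compound) cell from
# a peak table holding base, single-species, and pair filtrates.
# Replicate samples within a lineage are averaged first.
crossfeed_deltas <- function(profiles) {
  pp <- as_peak_profiles(profiles)
  assert_that(all(c("lineage", "treatment") %in% names(pp$meta)),
              "profiles need lineage and treatment metadata")
  base_rows <- pp$meta$lineage == "base"
  assert_that(any(base_rows), "no base-medium samples")
  base_mean <- colMeans(pp$values[base_rows, , drop = FALSE])
  cell_mean <- function(tr, lin) {
    sel <- !is.na(pp$meta$treatment) & pp$meta$treatment == tr &
      pp$meta$lineage == lin
    if (!any(sel)) return(NULL)
    colMeans(pp$values[sel, , drop = FALSE])
  }
  pair_meta <- pp$meta |>
    dplyr::filter(grepl(">", .data$lineage)) |>
    dplyr::distinct(.data$treatment, .data$lineage)
  out <- list()
  for (k in seq_len(nrow(pair_meta))) {
    tr <- pair_meta$treatment[k]
    lin <- pair_meta$lineage[k]
    sp <- strsplit(lin, ">", fixed = TRUE)[[1]]
    f1 <- cell_mean(tr, sp[1])
    f2 <- cell_mean(tr, lin)
    if (is.null(f1) || is.null(f2)) next
    d01 <- delta_01(f1, base_mean)
    d12 <- delta_12(f2, f1)
    out[[length(out) + 1]] <- tibble::tibble(
      first_species = sp[1], second_species = sp[2], treatment = tr,
      compound = names(d01), delta01 = unname(d01), delta12 = unname(d12))
  }
  dplyr::bind_rows(out)
}

#' Build the cross-feeding record table (production vs consumption shifts)
#'
#' For every matched (first species, second species, compound) the record
#' compares evolved against ancestral assays of the same pair:
#' `x = delta_01(evolved) - delta_01(ancestral)` (how much more the first
#' species produces after evolving) and
#' `y = delta_12(evolved) - delta_12(ancestral)` (how much more the
#' second species consumes). Only compounds actually produced by the
#' evolved first isolate (`delta_01(evolved) > 0`) are kept, focusing on
#' waste products as cross-feeding targets.
#'
#' @param evolved Long tibble with columns `first_species`,
#'   `second_species`, `treatment` (monoculture/polyculture), `compound`,
#'   `delta01`, `delta12` (e.g. from the internal delta builder used by
#'   [run_pipeline()]).
#' @param ancestral Same columns for ancestral assays (any `treatment`
#'   value; matching is by pair and compound).
#' @return Tibble of cross-feed records: `first_species`,
#'   `second_species`, `treatment`, `compound`, `x`, `y`. Pairs missing an
#'   ancestral counterpart are skipped with a warning.
#' @export
build_crossfeed_table <- function(evolved, ancestral) {
  need <- c("first_species", "second_species", "compound",
            "delta01", "delta12")
  assert_that(all(c(need, "treatment") %in% names(evolved)),
              "evolved table missing required columns")
  assert_that(all(need %in% names(ancestral)),
              "ancestral table missing required columns")
  anc <- ancestral |>
    dplyr::select("first_species", "second_species", "compound",
                  anc01 = "delta01", anc12 = "delta12")
  joined <- dplyr::left_join(evolved, anc,
                             by = c("first_species", "second_species",
                                    "compound"))
  missing <- joined |>
    dplyr::filter(is.na(.data$anc01)) |>
    dplyr::distinct(.data$first_species, .data$second_species)
  if (nrow(missing) > 0) {
    warning("no ancestral counterpart for pair(s): ",
            paste(missing$first_species, "->", missing$second_species,
                  collapse = "; "), "; skipped")
  }
  joined |>
    dplyr::filter(!is.na(.data$anc01), .data$delta01 > 0) |>
    dplyr::mutate(x = .data$delta01 - .data$anc01,
                  y = .data$delta12 - .data$anc12) |>
    dplyr::select("first_species", "second_species", "treatment",
                  "compound", "x", "y")
}

#' Pearson correlation of production and consumption shifts per treatment
#'
#' @param records Cross-feed records from [build_crossfeed_table()];
#'   >= 3 records per treatment required.
#' @return Tibble with one row per treatment: `treatment`, `r`,
#'   `statistic` (t), `df`, `p`, `n`.
#' @export
correlation_by_treatment <- function(records) {
  assert_that(nrow(records) > 0, "no records")
  out <- records |>
    dplyr::group_by(.data$treatment) |>
    dplyr::group_modify(function(d, key) {
      assert_that(nrow(d) >= 3, "need >= 3 records per treatment")
      assert_that(sd(d$x) > 0 && sd(d$y) > 0,
                  "zero variance in x or y; correlation undefined")
      ct <- cor.test(d$x, d$y)
      tibble::tibble(r = unname(ct$estimate),
                     statistic = unname(ct$statistic),
                     df = unname(ct$parameter), p = ct$p.value,
                     n = nrow(d))
    }) |>
    dplyr::ungroup()
  out
}

#' Interaction linear model: does the production/consumption slope differ
#' between treatments?
#'
#' Least-squares fit of `y ~ x * treatment` with monoculture as the
#' reference level; the interaction coefficient equals
#' slope(polyculture) - slope(monoculture).
#'
#' @param records Cross-feed records containing both `monoculture` and
#'   `polyculture` treatments (>= 3 records each).
#' @return List with `model` (the `lm` fit), `slopes` (named per-treatment
#'   slopes), and `interaction` (`estimate`, `se`, `t`, `p`).
#' @export
interaction_model <- function(records) {
  trs <- unique(records$treatment)
  assert_that(all(c("monoculture", "polyculture") %in% trs),
              "both monoculture and polyculture records required")
  counts <- table(records$treatment)
  assert_that(all(counts[c("monoculture", "polyculture")] >= 3),
              "need >= 3 records per treatment")
  df <- records
  df$treatment <- factor(df$treatment,
                         levels = c("monoculture", "polyculture"))
  fit <- lm(y ~ x * treatment, data = df)
  sm <- suppressWarnings(summary(fit))$coefficients # exact fits are valid input
  slope_mono <- coef(fit)[["x"]]
  inter <- sm["x:treatmentpolyculture", ]
  list(model = fit,
       slopes = c(monoculture = slope_mono,
                  polyculture = slope_mono + unname(inter["Estimate"])),
       interaction = list(estimate = unname(inter["Estimate"]),
                          se = unname(inter["Std. Error"]),
                          t = unname(inter["t value"]),
                          p = unname(inter["Pr(>|t|)"])))
}
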