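#' Simulate an NMR peak table for base medium, filtrates, and pair filtrates
#'
#' Emulates the metabolic-footprint assay: samples of the unused base
#' medium, medium used by each single species, and (optionally) medium used
#' by one species and then a second species of the same treatment. True
#' compositions come from [simulate_used_tea()]; Gaussian noise (truncated
#' at zero) is added per sample.
#'
#' @param configs Named list of evolved [community_config()]s, one per
#'   treatment (`ancestral`, `monoculture`, `polyculture`).
#' @param n_rep Replicate samples per lineage.
#' @param pairs If `TRUE`, include two-species ("first then second")
#'   filtrates for all ordered pairs within each treatment.
#' @param seed Integer seed.
#' @return Long tibble with columns `sample_id`, `peak_id`, `integral`,
#'   `species`, `treatment`, `lineage`.
#' @export
simulate_peak_table <- function(configs, n_rep = 3, pairs = TRUE, seed = 1) {
  assert_that(all(names(configs) %in% TREATMENTS) && length(configs) >= 1,
              "configs must be a named list keyed by treatment")
  base_cfg <- configs[[1]]
  compounds <- base_cfg$compound_ids
  noisy <- function(truth, key) {
    set.seed(child_seed(seed, "peaks", key))
    pmax(0, truth + rnorm(length(truth), 0, base_cfg$noise_peak))
  }
  rows <- list()
  add <- function(id, values, species, treatment, lineage) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      sample_id = id, peak_id = compounds, integral = as.numeric(values),
      species = species, treatment = treatment, lineage = lineage)
  }
  for (rep in seq_len(n_rep)) {
    add(sprintf("base_r%d", rep), noisy(base_cfg$base_medium, paste0("base", rep)),
        NA_character_, NA_character_, "base")
  }
  for (tr in names(configs)) {
    cfg <- configs[[tr]]
    for (sp in cfg$species_ids) {
      f1_true <- simulate_used_tea(cfg, sp)
      for (rep in seq_len(n_rep)) {
        add(sprintf("%s_%s_r%d", tr, sp, rep),
            noisy(f1_true, paste(tr, sp, rep)), sp, tr, sp)
      }
      if (pairs) {
        for (sp2 in setdiff(cfg$species_ids, sp)) {
          f2_true <- simulate_used_tea(cfg, sp2, medium = f1_true)
          for (rep in seq_len(n_rep)) {
            add(sprintf("%s_%s.%s_r%d", tr, sp, sp2, rep),
                noisy(f2_true, paste(tr, sp, sp2, rep)),
                sp2, tr, paste0(sp, ">", sp2))
          }
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

# Fraction of the base medium consumable by the community (union over
# species); the generator's link between evolved resource use and
# community respiration.
medium_coverage <- function(config) {
  sum(config$base_medium * apply(config$U, 2, max)) / sum(config$base_medium)
}

#' Simulate a MicroResp respiration plate
#'
#' Communities assembled from monoculture- or polyculture-evolved isolates
#' respire in proportion to how much of the medium the community can
#' jointly consume ([medium_coverage()]). The planted percent CO2 is pushed
#' through the inverse cresol-red calibration to give indicator OD570
#' readings at 0 and `incubation_h` hours, with blank wells carrying the
#' zero-respiration baseline.
#'
#' @param configs Named list with `monoculture` and `polyculture` evolved
#'   [community_config()]s.
#' @param n_rep Replicate community wells per group.
#' @param n_blank Blank wells.
#' @param calibration Named vector `c(A, B, D)` of indicator-curve
#'   constants.
#' @param incubation_h Incubation time, hours.
#' @param od_t0_mean Mean time-zero indicator OD570.
#' @param blank_ratio Indicator drift of blank wells over the incubation.
#' @param noise SD of Gaussian noise on OD570 readings.
#' @param seed Integer seed.
#' @return Tibble with columns `well`, `community_id`, `group`,
#'   `od570_t0`, `od570_t_end`, `blank`, plus the planted percent CO2 in
#'   `pct_co2_true` (NA for blanks).
#' @export
simulate_respiration <- function(configs, n_rep = 10, n_blank = 4,
                                 calibration = c(A = -0.2265, B = -1.606, D = -6.771),
                                 incubation_h = 6, od_t0_mean = 1,
                                 blank_ratio = 0.97, noise = 0.005, seed = 1) {
  assert_that(all(c("monoculture", "polyculture") %in% names(configs)),
              "configs must contain monoculture and polyculture entries")
  set.seed(child_seed(seed, "respiration"))
  A <- calibration[["A"]]; B <- calibration[["B"]]; D <- calibration[["D"]]
  baseline_pct <- A + B / (1 + D)
  ai_from_pct <- function(pct) (B / (pct - A) - 1) / D
  rows <- list()
  well_i <- 0
  add_well <- function(community_id, group, pct_net, blank) {
    well_i <<- well_i + 1
    od0 <- rnorm(1, od_t0_mean, 0.02)
    ai <- if (blank) 1 else ai_from_pct(baseline_pct + pct_net)
    rows[[length(rows) + 1]] <<- tibble::tibble(
      well = sprintf("W%02d", well_i), community_id = community_id,
      group = group, od570_t0 = od0,
      od570_t_end = max(0, ai * blank_ratio * od0 + rnorm(1, 0, noise)),
      blank = blank, pct_co2_true = if (blank) NA_real_ else baseline_pct + pct_net)
  }
  for (g in c("monoculture", "polyculture")) {
    cov <- medium_coverage(configs[[g]])
    for (rep in seq_len(n_rep)) {
      pct_net <- max(0.02, 0.1 + 0.8 * cov + rnorm(1, 0, 0.03))
      add_well(sprintf("%s_%d", substr(g, 1, 4), rep), g, pct_net, FALSE)
    }
  }
  for (b in seq_len(n_blank)) add_well(NA_character_, "blank", 0, TRUE)
  out <- dplyr::bind_rows(rows)
  attr(out, "assay") <- list(calibration = calibration,
                             incubation_h = incubation_h,
                             headspace_ml = 1, medium_ml = 1,
                             temperature_c = 25)
  out
}

#' Simulate the full five-table experiment
#'
#' Generates, from one ground-truth [community_config()], every input the
#' analysis pipeline reads: growth-assay OD time series on unused and
#' used media (with sterile controls), OD calibration data, NMR peak
#' tables, serial-transfer logs, and a MicroResp respiration plate. The
#' `truth` element retains the ancestral and per-treatment evolved
#' configurations so every downstream expectation can be recomputed.
#'
#' @param config Ancestral [community_config()].
#' @param effect_size Evolutionary effect size passed to
#'   [evolve_isolates()]; 0 gives identical parameters in all treatments.
#' @param seed Master integer seed; all sub-simulations derive child seeds
#'   deterministically from it.
#' @param n_rep_growth Growth-assay replicates per species x treatment x
#'   substrate (the experiment used 9).
#' @param n_rep_peaks NMR replicates per lineage.
#' @param times Growth-assay reading times, hours (daily over 4 days).
#' @param n_transfers,dilution Serial-transfer regime (15 transfers,
#'   20-fold).
#' @param pairs Include two-species filtrates in the peak table.
#' @param tables Character subset of
#'   `c("growth", "calibration", "peaks", "transfers", "respiration")` to
#'   generate (others are returned as `NULL`).
#' @return Object of class `synthetic_dataset`: a list with elements
#'   `growth`, `calibration`, `peaks`, `transfers`, `respiration`, `truth`.
#' @export
simulate_dataset <- function(config, effect_size = 1, seed = 1,
                             n_rep_growth = 9, n_rep_peaks = 3,
                             times = seq(0, 96, by = 24),
                             n_transfers = 15, dilution = 20, pairs = TRUE,
                             tables = c("growth", "calibration", "peaks",
                                        "transfers", "respiration")) {
  stopifnot(inherits(config, "community_config"))
  tables <- match.arg(tables, several.ok = TRUE)
  configs <- lapply(setNames(TREATMENTS, TREATMENTS), function(tr) {
    evolve_isolates(config, tr, effect_size = effect_size)
  })

  growth <- NULL
  if ("growth" %in% tables) {
    parts <- list()
    for (tr in TREATMENTS) {
      cfg <- configs[[tr]]
      media <- c(list(unused = cfg$base_medium),
                 setNames(lapply(cfg$species_ids, function(d)
                   simulate_used_tea(cfg, d)),
                   paste0("used:", cfg$species_ids)))
      for (sp in cfg$species_ids) {
        for (sub in names(media)) {
          for (rep in seq_len(n_rep_growth)) {
            parts[[length(parts) + 1]] <- simulate_growth_curve(
              cfg, sp, tr, rep, medium = media[[sub]], times = times,
              seed = child_seed(seed, "growth", tr, sp, sub, rep),
              substrate = sub, plate = paste(tr, sp, sub, sep = "_"),
              column = rep)
          }
        }
      }
    }
    growth <- dplyr::bind_rows(parts)
  }

  calibration <- if ("calibration" %in% tables) {
    simulate_calibration(config, seed = child_seed(seed, "calibration"))
  }
  peaks <- if ("peaks" %in% tables) {
    simulate_peak_table(configs, n_rep = n_rep_peaks, pairs = pairs,
                        seed = child_seed(seed, "peaktable"))
  }
  transfers <- if ("transfers" %in% tables) {
    simulate_serial_transfer(config, n_transfers = n_transfers,
                             dilution = dilution,
                             seed = child_seed(seed, "transfers"))
  }
  respiration <- if ("respiration" %in% tables) {
    simulate_respiration(configs, seed = child_seed(seed, "respiration"))
  }

  structure(list(growth = growth, calibration = calibration, peaks = peaks,
                 transfers = transfers, respiration = respiration,
                 truth = list(config = config, configs = configs,
                              effect_size = effect_size, seed = seed,
                              n_rep_growth = n_rep_growth,
                              n_rep_peaks = n_rep_peaks, times = times,
                              n_transfers = n_transfers, dilution = dilution)),
            class = "synthetic_dataset")
}

#' Simulate a null dataset with no treatment or species structure
#'
#' A type-I-error harness for the permutation tests: `effect_size` is fixed
#' at 0 so treatments are identical, and additionally every species'
#' parameters (`U`, `P`, `r`, `K`, calibration intercepts) are replaced by
#' the community means so that all profiles are fully exchangeable — the
#' condition assumed by the label-shuffling permutation scheme.
#'
#' @inheritParams simulate_dataset
#' @return A `synthetic_dataset` (see [simulate_dataset()]).
#' @export
simulate_null_dataset <- function(config, seed = 1,
                                  tables = c("growth", "calibration", "peaks",
                                             "transfers", "respiration"),
                                  n_rep_growth = 9, n_rep_peaks = 3,
                                  pairs = TRUE) {
  stopifnot(inherits(config, "community_config"))
  ns <- length(config$species_ids)
  null_cfg <- config
  null_cfg$U <- matrix(colMeans(config$U), ns, ncol(config$U), byrow = TRUE,
                       dimnames = dimnames(config$U))
  null_cfg$P <- matrix(colMeans(config$P), ns, ncol(config$P), byrow = TRUE,
                       dimnames = dimnames(config$P))
  null_cfg$r[] <- mean(config$r)
  null_cfg$K[] <- mean(config$K)
  null_cfg$cal_intercepts[] <- mean(config$cal_intercepts)
  simulate_dataset(null_cfg, effect_size = 0, seed = seed, tables = tables,
                   n_rep_growth = n_rep_growth, n_rep_peaks = n_rep_peaks,
                   pairs = pairs)
}

#' Write a synthetic dataset to CSV files plus a manifest
#'
#' Writes the five input tables as UTF-8 CSVs with a header row and "."
#' decimal separator, and a `manifest.yml` recording the generating
#' configuration, seed, and simulation settings.
#'
#' @param dataset A `synthetic_dataset` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (nm in c("growth", "calibration", "peaks", "transfers", "respiration")) {
    if (is.null(dataset[[nm]])) next
    p <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(dataset[[nm]], p)
    paths[nm] <- p
  }
  cfg <- dataset$truth$config
  manifest <- list(
    generator = "microcosm::simulate_dataset",
    seed = dataset$truth$seed,
    effect_size = dataset$truth$effect_size,
    species = as.list(cfg$species_ids),
    compounds = as.list(cfg$compound_ids),
    base_medium = as.list(unname(cfg$base_medium)),
    r = as.list(unname(cfg$r)),
    K = as.list(unname(cfg$K)),
    coupling = cfg$coupling,
    noise_od = cfg$noise_od, noise_peak = cfg$noise_peak,
    cal_slope = cfg$cal_slope,
    cal_intercepts = as.list(unname(cfg$cal_intercepts)),
    n_rep_growth = dataset$truth$n_rep_growth,
    n_rep_peaks = dataset$truth$n_rep_peaks,
    n_transfers = dataset$truth$n_transfers,
    dilution = dataset$truth$dilution)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yml"))
  paths["manifest"] <- file.path(dir, "manifest.yml")
  invisible(paths)
}
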