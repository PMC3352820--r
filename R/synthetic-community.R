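#' Ground-truth configuration of a synthetic bacterial community
#'
#' A `community_config` records everything needed to emulate the wet-lab
#' experiment: which compounds the growth medium contains, how much of each
#' compound every species consumes (`U`, fractions in \[0, 1\]) and produces
#' (`P`, amounts per growth cycle), intrinsic growth rates `r`
#' (doublings/day), carrying capacities `K` (cells/ml), the OD600-to-density
#' calibration used to render optical densities, and the measurement noise
#' levels. `coupling` scales how strongly polyculture-evolved isolates shift
#' their consumption onto compounds produced by other species
#' (cross-feeding).
#'
#' @param species_ids Character vector of unique species labels.
#' @param compound_ids Character vector of unique compound (peak) labels.
#' @param base_medium Named non-negative vector of compound amounts in the
#'   unused medium (dimensionless, relative to the internal standard).
#' @param r Per-species intrinsic growth rate, doublings/day.
#' @param K Per-species carrying capacity, cells/ml.
#' @param U Species x compound consumption-fraction matrix, entries in
#'   \[0, 1\].
#' @param P Species x compound production matrix, non-negative amounts.
#' @param coupling Non-negative scalar controlling evolved cross-feeding.
#' @param noise_od SD of Gaussian OD600 measurement noise.
#' @param noise_peak SD of Gaussian peak-integral noise (truncated at 0).
#' @param cal_slope Calibration slope: log10 cells/ml per OD600 unit.
#' @param cal_intercepts Per-species calibration intercepts, log10 cells/ml
#'   at OD600 = 0.
#' @param n0_frac Inoculum density as a fraction of `K`.
#' @param phi_max Upper cap on the resource-sufficiency factor; values above
#'   1 let spent medium enriched in a species' preferred substrates support
#'   faster-than-baseline growth (facilitation).
#' @param blank_od Additive OD600 of sterile medium (removed by blank
#'   correction).
#' @param seed Integer seed recorded with the configuration.
#' @return An object of class `community_config`.
#' @seealso [make_default_community()], [evolve_isolates()]
#' @export
community_config <- function(species_ids, compound_ids, base_medium, r, K, U, P,
                             coupling = 1, noise_od = 0.01, noise_peak = 0.05,
                             cal_slope = 3,
                             cal_intercepts = setNames(rep(5, length(species_ids)), species_ids),
                             n0_frac = 1e-3, phi_max = 2, blank_od = 0.05,
                             seed = NULL) {
  ns <- length(species_ids)
  nc <- length(compound_ids)
  assert_that(ns >= 1 && !anyDuplicated(species_ids), "species_ids must be unique")
  assert_that(nc >= 1 && !anyDuplicated(compound_ids), "compound_ids must be unique")
  U <- as.matrix(U); P <- as.matrix(P)
  assert_that(all(dim(U) == c(ns, nc)), "U must be species x compound")
  assert_that(all(dim(P) == c(ns, nc)), "P must be species x compound")
  assert_that(all(U >= 0 & U <= 1), "U entries must lie in [0, 1]")
  assert_that(all(P >= 0), "P entries must be non-negative")
  assert_that(length(base_medium) == nc && all(base_medium >= 0),
              "base_medium must be non-negative, one entry per compound")
  assert_that(length(r) == ns && all(r >= 0), "r must be non-negative, one per species")
  assert_that(length(K) == ns && all(K > 0), "K must be positive, one per species")
  assert_that(length(coupling) == 1 && coupling >= 0, "coupling must be >= 0")
  assert_that(noise_od >= 0 && noise_peak >= 0, "noise terms must be non-negative")
  dimnames(U) <- dimnames(P) <- list(species_ids, compound_ids)
  structure(list(
    species_ids = species_ids, compound_ids = compound_ids,
    base_medium = setNames(as.numeric(base_medium), compound_ids),
    r = setNames(as.numeric(r), species_ids),
    K = setNames(as.numeric(K), species_ids),
    U = U, P = P, coupling = coupling,
    noise_od = noise_od, noise_peak = noise_peak,
    cal_slope = cal_slope,
    cal_intercepts = setNames(as.numeric(cal_intercepts), species_ids),
    n0_frac = n0_frac, phi_max = phi_max, blank_od = blank_od,
    seed = seed
  ), class = "community_config")
}

#' @export
print.community_config <- function(x, ...) {
  cat("<community_config>\n")
  cat("  species:  ", paste(x$species_ids, collapse = ", "), "\n")
  cat("  compounds:", length(x$compound_ids),
      sprintf("(%d consumed by >1 species)",
              sum(colSums(x$U > 0) > 1)), "\n")
  cat("  r:", paste(signif(x$r, 3), collapse = ", "), "doublings/day\n")
  cat("  coupling:", x$coupling,
      " noise_od:", x$noise_od, " noise_peak:", x$noise_peak, "\n")
  invisible(x)
}

#' Build a default random community with overlapping resource use
#'
#' Compounds are split into nutrients (abundant in the unused medium) and
#' waste products (scarce in the medium, only produced by growth). A core
#' set of nutrients is consumed by every species, guaranteeing niche overlap
#' so that ancestral spent-medium interactions are negative; remaining
#' nutrients are assigned to random subsets of species. Each species
#' produces one waste compound.
#'
#' @param n_species Number of species (>= 2).
#' @param n_compounds Number of compounds (>= 2).
#' @param seed Integer seed; identical `(n_species, n_compounds, seed)`
#'   return identical configurations.
#' @inheritParams community_config
#' @return A [community_config()].
#' @export
make_default_community <- function(n_species, n_compounds, seed = 1,
                                   coupling = 1, noise_od = 0.01,
                                   noise_peak = 0.05) {
  assert_that(is_count(n_species) && n_species >= 2, "n_species must be a count >= 2")
  assert_that(is_count(n_compounds) && n_compounds >= 2, "n_compounds must be a count >= 2")
  set.seed(child_seed(seed, "default_community", n_species, n_compounds))
  species_ids <- LETTERS[seq_len(n_species)]
  compound_ids <- sprintf("c%02d", seq_len(n_compounds))

  n_waste <- max(1, min(n_compounds - 1, round(n_compounds / 4)))
  waste <- seq(n_compounds - n_waste + 1, n_compounds)
  nutrients <- setdiff(seq_len(n_compounds), waste)
  n_core <- max(1, ceiling(length(nutrients) / 2))
  core <- nutrients[seq_len(n_core)]

  base_medium <- numeric(n_compounds)
  base_medium[nutrients] <- runif(length(nutrients), 0.5, 1.5)
  base_medium[waste] <- 0.05

  U <- matrix(0, n_species, n_compounds)
  U[, core] <- runif(n_species * length(core), 0.4, 0.8)
  extra <- setdiff(nutrients, core)
  if (length(extra) > 0) {
    member <- matrix(runif(n_species * length(extra)) < 0.4, n_species)
    U[, extra] <- member * runif(n_species * length(extra), 0.2, 0.6)
  }

  P <- matrix(0, n_species, n_compounds)
  for (i in seq_len(n_species)) {
    P[i, waste[1 + (i - 1) %% length(waste)]] <- runif(1, 0.4, 1.0)
  }

  # dilute leaf-extract medium: carrying capacities of order 1e7 cells/ml,
  # so twice-weekly 20-fold dilution gives bottleneck-x-generations
  # effective sizes of a few million cells
  K <- 10^runif(n_species, 6.8, 7.3)
  community_config(
    species_ids = species_ids, compound_ids = compound_ids,
    base_medium = base_medium,
    r = runif(n_species, 2, 3.5),
    K = K,
    U = U, P = P, coupling = coupling,
    noise_od = noise_od, noise_peak = noise_peak,
    cal_slope = 3,
    # intercept tied to K so the assay's OD span stays on-scale: the
    # inoculum (K/1000) reads near OD 0.13 and saturation near OD 1.1
    cal_intercepts = setNames(log10(K) - 3.4 + runif(n_species, -0.2, 0.2),
                              species_ids),
    seed = seed
  )
}

#' Derive the evolved parameters of isolates under a diversity treatment
#'
#' Emulates the direction of evolution observed in the experiment without
#' fitting it: `ancestral` returns the configuration unchanged; in
#' `monoculture` every species' growth rate increases and its consumption
#' profile is pulled toward the community mean (convergent adaptation to
#' the medium); in `polyculture` consumption profiles are pushed apart
#' (character displacement), consumption is added on compounds other
#' species produce with weight `coupling * effect_size` (cross-feeding),
#' and production of waste compounds increases.
#'
#' @param config A [community_config()].
#' @param treatment One of `"ancestral"`, `"monoculture"`, `"polyculture"`.
#' @param effect_size Non-negative scalar; 0 returns `config` unchanged for
#'   every treatment.
#' @param seed Unused (the evolutionary shift is deterministic); kept so the
#'   call signature matches the other simulators.
#' @return A [community_config()] with evolved `r`, `U`, `P`.
#' @export
evolve_isolates <- function(config, treatment, effect_size = 1, seed = NULL) {
  stopifnot(inherits(config, "community_config"))
  check_treatment(treatment)
  assert_that(length(effect_size) == 1 && effect_size >= 0,
              "effect_size must be a non-negative scalar")
  if (treatment == "ancestral" || effect_size == 0) return(config)

  U <- config$U
  P <- config$P
  r <- config$r
  ubar <- matrix(colMeans(U), nrow(U), ncol(U), byrow = TRUE)

  if (treatment == "monoculture") {
    # convergent adaptation to the medium: pull toward the community mean
    U <- U + min(1, 0.5 * effect_size) * (ubar - U)
    r <- r * (1 + 0.4 * effect_size)
  } else { # polyculture
    # character displacement: push apart, about twice the monoculture
    # magnitude (polyculture isolates changed roughly twice as much as
    # monoculture isolates in the experiment)
    U <- U + min(1.5, effect_size) * (U - ubar)
    U <- pmin(pmax(U, 0), 1)
    for (i in seq_len(nrow(U))) {
      others_produce <- colSums(P[-i, , drop = FALSE]) > 0
      U[i, others_produce] <- pmin(1, U[i, others_produce] +
                                     0.5 * config$coupling * effect_size)
    }
    P <- P * (1 + 0.3 * effect_size * (P > 0))
  }
  out <- config
  out$U <- pmin(pmax(U, 0), 1)
  out$P <- P
  out$r <- r
  out
}

# Mean Euclidean distance between species' consumption-profile rows.
mean_row_distance <- function(U) {
  mean(dist(U))
}

# Resource-sufficiency factor: consumable resource in `medium` relative to
# the unused base medium, capped at [0, phi_max]. phi(base) == 1; spent
# medium enriched in a species' substrates can push phi above 1 (up to
# phi_max), which is how facilitation arises in the generator.
resource_sufficiency <- function(config, species, medium) {
  u <- config$U[species, ]
  den <- sum(u * config$base_medium)
  if (den <= 0) return(1)
  min(config$phi_max, max(0, sum(u * medium) / den))
}

#' Compose spent ("used") medium after growth of one species
#'
#' Each compound is reduced by the species' consumption fraction and
#' incremented by its production: `used = medium * (1 - U[i, ]) + P[i, ]`.
#' The result is non-negative for any valid configuration.
#'
#' @param config A [community_config()] (already evolved, if applicable).
#' @param species Species label present in `config`.
#' @param medium Non-negative compound vector (defaults to the base medium).
#' @return Named compound vector of the spent medium.
#' @export
simulate_used_tea <- function(config, species, medium = config$base_medium) {
  stopifnot(inherits(config, "community_config"))
  assert_that(species %in% config$species_ids,
              sprintf("species '%s' not in config", species))
  assert_that(length(medium) == length(config$compound_ids) && all(medium >= 0),
              "medium must be non-negative, one entry per compound")
  medium * (1 - config$U[species, ]) + config$P[species, ]
}

# Logistic growth: N(t) = K N0 e^(rho t) / (K + N0 (e^(rho t) - 1)),
# rho in 1/day, t in days. K = Inf gives the exponential limit.
logistic_density <- function(n0, K, rho, t_days) {
  if (!is.finite(K)) return(n0 * exp(rho * t_days))
  e <- exp(rho * t_days)
  K * n0 * e / (K + n0 * (e - 1))
}

od_from_density <- function(config, species, n) {
  (log10(n) - config$cal_intercepts[species]) / config$cal_slope
}

#' Simulate one growth-assay well (plus its sterile control)
#'
#' Cell density follows logistic growth at rate
#' `rho = r * ln(2) * phi(medium)` per day, where `phi` is the fraction of
#' the isolate's consumable resource present in `medium` relative to the
#' unused base medium (capped at `phi_max`). Optical density is rendered by
#' inverting the OD600 calibration, adding the sterile-medium blank and
#' Gaussian noise. Sterile-control rows for the same plate column are
#' included so that downstream blank correction can be exercised.
#'
#' @param config A [community_config()] already evolved for the isolate's
#'   treatment.
#' @param species,treatment,replicate Isolate label components (metadata).
#' @param medium Compound vector of the assay medium.
#' @param times Non-negative, sorted reading times in hours.
#' @param seed Integer seed; `NULL` leaves the RNG stream untouched.
#' @param substrate Lineage descriptor recorded in the table (e.g.
#'   `"unused"` or `"used:A"`).
#' @param n0 Inoculum density, cells/ml (default `n0_frac * K`).
#' @param plate,column Plate layout metadata used for blank matching.
#' @return Tibble with columns `plate`, `well`, `column`, `species`,
#'   `treatment`, `replicate`, `substrate`, `time_h`, `od600`,
#'   `is_control`.
#' @export
simulate_growth_curve <- function(config, species, treatment, replicate,
                                  medium = config$base_medium,
                                  times = seq(0, 96, by = 24),
                                  seed = NULL, substrate = "unused",
                                  n0 = NULL, plate = "P1", column = 1L) {
  stopifnot(inherits(config, "community_config"))
  assert_that(all(medium >= 0), "medium entries must be non-negative")
  assert_that(all(times >= 0) && !is.unsorted(times), "times must be sorted, non-negative")
  if (!is.null(seed)) set.seed(seed)
  phi <- resource_sufficiency(config, species, medium)
  rho <- config$r[species] * log(2) * phi
  K <- config$K[species]
  n0 <- n0 %||% (config$n0_frac * K)
  n <- logistic_density(n0, K, rho, times / 24)
  od_true <- od_from_density(config, species, n)
  nt <- length(times)
  meas <- tibble::tibble(
    plate = plate, well = paste0("A", column), column = as.integer(column),
    species = species, treatment = treatment, replicate = as.integer(replicate),
    substrate = substrate, time_h = as.numeric(times),
    od600 = pmax(0, od_true + config$blank_od + rnorm(nt, 0, config$noise_od)),
    is_control = FALSE
  )
  ctrl <- tibble::tibble(
    plate = plate, well = paste0("D", column), column = as.integer(column),
    species = NA_character_, treatment = NA_character_, replicate = NA_integer_,
    substrate = substrate, time_h = as.numeric(times),
    od600 = pmax(0, config$blank_od + rnorm(nt, 0, config$noise_od)),
    is_control = TRUE
  )
  dplyr::bind_rows(meas, ctrl)
}

#' Simulate OD600-to-colony-count calibration data
#'
#' Draws OD values and renders colony counts from the configuration's
#' shared-slope, species-intercept calibration with lognormal (Gaussian on
#' log10) noise.
#'
#' @param config A [community_config()].
#' @param n_per_species Number of calibration points per species.
#' @param od_range Range of OD600 values sampled.
#' @param noise_log10 SD of Gaussian noise on log10 colony counts.
#' @param seed Integer seed.
#' @return Tibble with columns `species`, `od600`, `colonies_per_ml`.
#' @export
simulate_calibration <- function(config, n_per_species = 20,
                                 od_range = c(0.05, 1), noise_log10 = 0.15,
                                 seed = NULL) {
  stopifnot(inherits(config, "community_config"))
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(config$species_ids, function(s) {
    od <- runif(n_per_species, od_range[1], od_range[2])
    lg <- config$cal_intercepts[s] + config$cal_slope * od +
      rnorm(n_per_species, 0, noise_log10)
    tibble::tibble(species = s, od600 = od, colonies_per_ml = 10^lg)
  })
  dplyr::bind_rows(out)
}

#' Simulate a serial-transfer log
#'
#' Each transfer dilutes the culture `dilution`-fold into fresh medium;
#' regrowth returns the culture to carrying capacity with multiplicative
#' lognormal noise. One culture per species is emitted; the log records
#' pre-transfer densities.
#'
#' @param config A [community_config()].
#' @param n_transfers Number of transfers (>= 1).
#' @param dilution Dilution factor (> 1); the experiment's regime was
#'   20-fold.
#' @param volume_ml Culture volume in ml.
#' @param noise Lognormal SD of regrowth densities (0 gives exactly `K`).
#' @param seed Integer seed.
#' @return Tibble with columns `culture_id`, `transfer`, `density_per_ml`,
#'   `dilution`, `volume_ml`.
#' @export
simulate_serial_transfer <- function(config, n_transfers = 15, dilution = 20,
                                     volume_ml = 2, noise = 0.1, seed = NULL) {
  stopifnot(inherits(config, "community_config"))
  assert_that(is_count(n_transfers), "n_transfers must be a count >= 1")
  assert_that(dilution > 1, "dilution must exceed 1")
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(config$species_ids, function(s) {
    dens <- config$K[s] * exp(rnorm(n_transfers, 0, noise))
    tibble::tibble(culture_id = s, transfer = seq_len(n_transfers),
                   density_per_ml = dens, dilution = dilution,
                   volume_ml = volume_ml)
  })
  dplyr::bind_rows(out)
}
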