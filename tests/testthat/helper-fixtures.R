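# Fixture builders and independent oracles used across the suite.

# Small hand-specified community for exact tests.
tiny_config <- function(U = NULL, P = NULL, base = NULL, ns = 2, nc = 3,
                        r = NULL, K = NULL, noise_od = 0, noise_peak = 0,
                        ...) {
  sp <- LETTERS[seq_len(ns)]
  cp <- sprintf("c%02d", seq_len(nc))
  U <- U %||% matrix(0.5, ns, nc)
  P <- P %||% matrix(0, ns, nc)
  community_config(
    species_ids = sp, compound_ids = cp,
    base_medium = base %||% rep(1, nc),
    r = r %||% rep(2, ns), K = K %||% rep(1e8, ns),
    U = U, P = P, noise_od = noise_od, noise_peak = noise_peak, ...)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Delta profiles object from a matrix with per-row species/treatment labels.
profiles_from_matrix <- function(mat, species, treatment) {
  colnames(mat) <- colnames(mat) %||% sprintf("p%02d", seq_len(ncol(mat)))
  peak_profiles(mat,
                tibble::tibble(sample_id = sprintf("s%02d", seq_len(nrow(mat))),
                               species = species, treatment = treatment),
                delta = TRUE)
}

# ---- independent oracles ------------------------------------------------

# Plain-loop Euclidean distance statistics, written independently of the
# package's distance-matrix indexing path.
oracle_evolution <- function(mat, species, treatment, evolved,
                             reference = "ancestral") {
  sp <- sort(unique(species))
  vals <- sapply(sp, function(s) {
    a <- which(species == s & treatment == reference)
    e <- which(species == s & treatment == evolved)
    m <- outer(a, e, Vectorize(function(i, j) sqrt(sum((mat[i, ] - mat[j, ])^2))))
    mean(m)
  })
  mean(vals)
}

oracle_divergence <- function(mat, species, treatment, within) {
  sel <- which(treatment == within)
  sp <- sort(unique(species[sel]))
  pairs <- utils::combn(sp, 2)
  vals <- apply(pairs, 2, function(pr) {
    a <- sel[species[sel] == pr[1]]
    b <- sel[species[sel] == pr[2]]
    m <- outer(a, b, Vectorize(function(i, j) sqrt(sum((mat[i, ] - mat[j, ])^2))))
    mean(m)
  })
  mean(vals)
}

# Lexicographic next-permutation enumeration (algorithmically distinct from
# the package's recursive generator).
oracle_all_perms <- function(n) {
  p <- seq_len(n)
  out <- list(p)
  repeat {
    i <- n - 1L
    while (i >= 1L && p[i] >= p[i + 1L]) i <- i - 1L
    if (i < 1L) break
    j <- n
    while (p[j] <= p[i]) j <- j - 1L
    tmp <- p[i]; p[i] <- p[j]; p[j] <- tmp
    p[(i + 1L):n] <- rev(p[(i + 1L):n])
    out[[length(out) + 1L]] <- p
  }
  out
}

# Exhaustive-enumeration oracle for the footprint permutation test.
oracle_exact_perm_p <- function(mat, species, treatment, statistic,
                                evolved = "monoculture",
                                within = "polyculture") {
  n <- nrow(mat)
  stat <- function(perm) {
    m <- mat[perm, , drop = FALSE]
    if (statistic == "evolution_distance") {
      oracle_evolution(m, species, treatment, evolved)
    } else {
      oracle_divergence(m, species, treatment, within)
    }
  }
  perms <- oracle_all_perms(n)
  draws <- vapply(perms, stat, numeric(1))
  obs <- stat(seq_len(n))
  eps <- 1e-9 * max(1, abs(obs))
  p_ge <- mean(draws >= obs - eps)
  p_le <- mean(draws <= obs + eps)
  min(1, 2 * min(p_ge, p_le))
}

# Exhaustive group-assignment oracle for the mean-difference test.
oracle_exact_diff_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  obs <- mean(x) - mean(y)
  idx <- utils::combn(n, nx)
  diffs <- apply(idx, 2, function(i) mean(pooled[i]) - mean(pooled[-i]))
  mean(abs(diffs) >= abs(obs) - 1e-9 * max(1, abs(obs)))
}

# True calibration model taken straight from a config (no fitting).
truth_calibration <- function(config) {
  structure(list(slope = config$cal_slope,
                 intercepts = config$cal_intercepts,
                 fit_stats = list(f = NA, df1 = NA, df2 = NA, r_squared = 1),
                 fit = NULL),
            class = "calibration_model")
}

# Noiseless expected delta profile of one species: P - U * base.
truth_delta_matrix <- function(config) {
  d <- t(vapply(config$species_ids, function(s) {
    config$P[s, ] - config$U[s, ] * config$base_medium
  }, numeric(length(config$compound_ids))))
  rownames(d) <- config$species_ids
  d
}

# Simulate used/unused growth assays for one treatment and return the
# V_MAX table (truth calibration; default 9 replicates as in the assays).
overlap_vmax_table <- function(config, seed, n_rep = 9,
                               treatment = "ancestral",
                               times = seq(0, 96, 24)) {
  media <- c(list(unused = config$base_medium),
             stats::setNames(lapply(config$species_ids, function(d)
               simulate_used_tea(config, d)),
               paste0("used:", config$species_ids)))
  parts <- list()
  for (sp in config$species_ids) {
    for (sub in names(media)) {
      for (rep in seq_len(n_rep)) {
        parts[[length(parts) + 1]] <- simulate_growth_curve(
          config, sp, treatment, rep, medium = media[[sub]], times = times,
          seed = microcosm:::child_seed(seed, sp, sub, rep),
          substrate = sub, plate = paste(sp, sub, sep = "_"), column = rep)
      }
    }
  }
  rows <- blank_correct(dplyr::bind_rows(parts))
  vmax_table(calibrate_growth(rows, truth_calibration(config)))
}

# Three-species config with a planted producer->consumer pair: species A
# produces a waste compound that species C is specialised on; A and B
# overlap on the nutrients.
crossfeed_config <- function(noise_od = 0.01) {
  U <- rbind(A = c(0.8, 0.8, 0),
             B = c(0.7, 0.7, 0),
             C = c(0.1, 0.0, 0.8))
  P <- matrix(0, 3, 3, dimnames = dimnames(U))
  P["A", 3] <- 0.8
  community_config(
    species_ids = c("A", "B", "C"), compound_ids = c("n1", "n2", "w"),
    base_medium = c(1, 1, 0.05), r = c(2.5, 2.5, 2.5),
    K = rep(4e8, 3), U = U, P = P, noise_od = noise_od, noise_peak = 0.05)
}
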