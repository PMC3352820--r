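#' Two-sided permutation test on a difference of group means
#'
#' The shared permutation engine behind [treatment_contrast()],
#' [interaction_effect()] and [compare_assemblies()]. Group labels are
#' permuted over the pooled observations; the two-sided p-value counts
#' permuted absolute differences at least as large as the observed one. In
#' Monte Carlo mode the add-one correction `p = (k + 1) / (B + 1)` is
#' applied (the observed arrangement counts as one permutation); in exact
#' mode all `choose(n, n_x)` group assignments are enumerated and the
#' p-value is the exact tail fraction.
#'
#' @param x,y Numeric vectors of observations in the two groups.
#' @param B Number of random permutations (Monte Carlo mode).
#' @param seed Integer seed for the permutation draw.
#' @param exact If `TRUE`, enumerate all assignments (requires
#'   `choose(n, n_x) <= 1e5`).
#' @return List with `observed` (mean(x) - mean(y)), `p`, `B`, `exact`,
#'   and `null_draws` (permuted differences, excluding the observed one in
#'   Monte Carlo mode).
#' @export
perm_diff_test <- function(x, y, B = 10000, seed = NULL, exact = FALSE) {
  assert_that(length(x) >= 1 && length(y) >= 1, "both groups must be non-empty")
  pooled <- c(x, y)
  nx <- length(x)
  n <- length(pooled)
  obs <- mean(x) - mean(y)
  if (exact) {
    idx <- combn(n, nx)
    total <- sum(pooled)
    diffs <- apply(idx, 2, function(i) {
      sx <- sum(pooled[i])
      sx / nx - (total - sx) / (n - nx)
    })
    # small tie tolerance so float summation order cannot miscount ties
    k <- sum(abs(diffs) >= abs(obs) - 1e-9 * max(1, abs(obs)))
    return(list(observed = obs, p = k / ncol(idx), B = ncol(idx),
                exact = TRUE, null_draws = diffs))
  }
  assert_that(is_count(B), "B must be a positive count")
  if (!is.null(seed)) set.seed(seed)
  total <- sum(pooled)
  draws <- vapply(seq_len(B), function(b) {
    i <- sample.int(n, nx)
    sx <- sum(pooled[i])
    sx / nx - (total - sx) / (n - nx)
  }, numeric(1))
  k <- sum(abs(draws) >= abs(obs) - 1e-9 * max(1, abs(obs)))
  list(observed = obs, p = (k + 1) / (B + 1), B = B, exact = FALSE,
       null_draws = draws)
}

# All permutations of 1..n as a matrix with n! columns (n <= 8).
all_permutations <- function(n) {
  assert_that(n >= 1 && n <= 8, "exhaustive enumeration limited to n <= 8")
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  cols <- vector("list", n * ncol(sub))
  k <- 0
  for (j in seq_len(ncol(sub))) {
    p <- sub[, j]
    for (pos in seq_len(n)) {
      k <- k + 1
      cols[[k]] <- append(p, n, after = pos - 1L)
    }
  }
  matrix(unlist(cols), nrow = n)
}

#' Monte Carlo permutation test on metabolic-footprint distances
#'
#' Implements the experiment's Monte Carlo significance tests: profiles are
#' shuffled uniformly at random among the (species, treatment) labels —
#' group sizes fixed — and the distance statistic is recomputed for each of
#' `B` shuffles. The two-tailed p-value doubles the smaller tail,
#' `p = min(1, 2 * min(P>=, P<=))`, with the observed arrangement counted
#' among the permutations (add-one correction in Monte Carlo mode). With
#' `exact = TRUE` all `n!` assignments of profiles to labels are
#' enumerated (limited to 8 profiles) and the tail probabilities are exact.
#'
#' Both built-in statistics depend on the profiles only through pairwise
#' Euclidean distances, so the distance matrix is computed once and each
#' permutation re-indexes it.
#'
#' @param profiles A [peak_profiles()] object of delta profiles with
#'   `species` and `treatment` metadata.
#' @param statistic `"evolution_distance"` (mean distance between a
#'   species' reference and evolved profiles, averaged over species),
#'   `"divergence_distance"` (mean between-species distance within one
#'   treatment), or a function `f(values_matrix, meta)` for custom
#'   statistics.
#' @param treatment Evolved treatment ([evolution_distance()]) or the
#'   treatment whose divergence is measured ([divergence_distance()]).
#' @param reference Reference treatment for `evolution_distance`
#'   (default `"ancestral"`).
#' @param B Number of random permutations (default 10000, the experiment's
#'   setting).
#' @param seed Integer seed.
#' @param exact Enumerate all assignments instead of sampling.
#' @return Object of class `perm_test`: list with `statistic_name`,
#'   `observed`, `null_draws`, `p_two_tailed`, `B`, `seed`, `exact`.
#' @export
permutation_test <- function(profiles, statistic = "divergence_distance",
                             treatment = "polyculture",
                             reference = "ancestral",
                             B = 10000, seed = NULL, exact = FALSE) {
  pp <- as_peak_profiles(profiles)
  meta <- pp$meta
  n <- nrow(pp$values)
  assert_that(n >= 2, "need at least 2 profiles")

  custom <- is.function(statistic)
  if (custom) {
    stat_fun <- function(perm) statistic(pp$values[perm, , drop = FALSE], meta)
    stat_name <- "custom"
  } else {
    statistic <- match.arg(statistic,
                           c("evolution_distance", "divergence_distance"))
    stat_name <- statistic
    D <- as.matrix(dist(pp$values))
    idx <- distance_pair_index(meta, statistic, treatment, reference)
    stat_fun <- function(perm) {
      sum(idx$w * D[cbind(perm[idx$i], perm[idx$j])])
    }
  }
  obs <- stat_fun(seq_len(n))
  # tie tolerance: permutations reproducing the observed pairing must count
  # as ties regardless of float summation order
  eps <- 1e-9 * max(1, abs(obs))

  if (exact) {
    perms <- all_permutations(n)
    draws <- apply(perms, 2, stat_fun)
    p_ge <- mean(draws >= obs - eps)
    p_le <- mean(draws <= obs + eps)
    B_used <- ncol(perms)
  } else {
    assert_that(is_count(B), "B must be a positive count")
    if (!is.null(seed)) set.seed(seed)
    draws <- vapply(seq_len(B), function(b) stat_fun(sample.int(n)),
                    numeric(1))
    p_ge <- (sum(draws >= obs - eps) + 1) / (B + 1)
    p_le <- (sum(draws <= obs + eps) + 1) / (B + 1)
    B_used <- B
  }
  structure(list(statistic_name = stat_name, observed = obs,
                 null_draws = draws,
                 p_two_tailed = min(1, 2 * min(p_ge, p_le)),
                 p_ge = p_ge, p_le = p_le,
                 B = B_used, seed = seed, exact = exact),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("<perm_test>", x$statistic_name, "\n")
  cat(sprintf("  observed = %.6g, p (two-tailed) = %.4g, %s %d permutations\n",
              x$observed, x$p_two_tailed,
              if (x$exact) "exhaustive over" else "Monte Carlo with", x$B))
  invisible(x)
}

# Precompute, for a statistic defined as a weighted mean of pairwise
# distances between label slots, the slot index pairs and weights.
distance_pair_index <- function(meta, statistic, treatment, reference) {
  pi <- integer(0); pj <- integer(0); w <- numeric(0)
  if (statistic == "evolution_distance") {
    species <- sort(unique(meta$species[meta$treatment %in% c(treatment, reference)]))
    assert_that(length(species) >= 1, "no species shared by the two treatments")
    for (s in species) {
      a <- which(meta$species == s & meta$treatment == reference)
      e <- which(meta$species == s & meta$treatment == treatment)
      assert_that(length(a) >= 1 && length(e) >= 1,
                  sprintf("species %s missing from a treatment", s))
      g <- expand.grid(a = a, e = e)
      pi <- c(pi, g$a); pj <- c(pj, g$e)
      w <- c(w, rep(1 / (length(species) * nrow(g)), nrow(g)))
    }
  } else {
    sel <- which(meta$treatment == treatment)
    species <- sort(unique(meta$species[sel]))
    assert_that(length(species) >= 2, "divergence needs >= 2 species")
    pairs <- combn(species, 2)
    for (k in seq_len(ncol(pairs))) {
      i1 <- sel[meta$species[sel] == pairs[1, k]]
      i2 <- sel[meta$species[sel] == pairs[2, k]]
      g <- expand.grid(a = i1, b = i2)
      pi <- c(pi, g$a); pj <- c(pj, g$b)
      w <- c(w, rep(1 / (ncol(pairs) * nrow(g)), nrow(g)))
    }
  }
  list(i = pi, j = pj, w = w)
}
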