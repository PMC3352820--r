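#' Peak-profile container
#'
#' Holds a samples x peaks matrix of NMR peak integrals (dimensionless,
#' relative to the internal standard) together with per-sample metadata.
#' The same container carries difference ("delta") profiles, where values
#' may be negative and positive values indicate net production.
#'
#' @param values Numeric matrix, samples in rows (rownames = sample ids),
#'   peaks in columns.
#' @param meta Tibble with one row per sample: `sample_id` plus any of
#'   `species`, `treatment`, `lineage`.
#' @param delta Logical; `TRUE` marks difference profiles.
#' @return Object of class `peak_profiles`.
#' @export
peak_profiles <- function(values, meta, delta = FALSE) {
  values <- as.matrix(values)
  assert_that(!is.null(colnames(values)) && !anyDuplicated(colnames(values)),
              "peak names must be present and unique")
  assert_that(nrow(values) == nrow(meta), "one meta row per sample required")
  assert_that("sample_id" %in% names(meta), "meta needs a sample_id column")
  if (!delta) assert_that(all(values >= 0), "raw peak integrals must be >= 0")
  rownames(values) <- meta$sample_id
  structure(list(values = values, meta = tibble::as_tibble(meta),
                 delta = delta),
            class = "peak_profiles")
}

as_peak_profiles <- function(x) {
  if (inherits(x, "peak_profiles")) return(x)
  stop("expected a peak_profiles object", call. = FALSE)
}

#' @export
print.peak_profiles <- function(x, ...) {
  cat(sprintf("<peak_profiles%s> %d samples x %d peaks\n",
              if (x$delta) " (delta)" else "", nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.peak_profiles <- function(x) dim(x$values)

#' Load a long-format NMR peak table into profiles
#'
#' @param x Path to a CSV, or a long tibble, with columns `sample_id`,
#'   `peak_id`, `integral` and metadata columns `species`, `treatment`,
#'   `lineage` (constant within a sample).
#' @param zero_fill If `TRUE`, absent (sample, peak) combinations become 0;
#'   by default they are an error so silently incomplete tables are caught.
#' @return A [peak_profiles()] object on the common peak axis.
#' @export
load_peak_table <- function(x, zero_fill = FALSE) {
  df <- if (is.character(x)) {
    readr::read_csv(x, show_col_types = FALSE)
  } else tibble::as_tibble(x)
  need <- c("sample_id", "peak_id", "integral")
  assert_that(all(need %in% names(df)),
              paste("missing columns:",
                    paste(setdiff(need, names(df)), collapse = ", ")))
  dup <- df |>
    dplyr::count(.data$sample_id, .data$peak_id) |>
    dplyr::filter(.data$n > 1)
  assert_that(nrow(dup) == 0,
              paste("duplicate (sample, peak) rows, e.g.",
                    paste(head(dup$sample_id, 3), head(dup$peak_id, 3),
                          collapse = "; ")))
  meta_cols <- intersect(c("species", "treatment", "lineage"), names(df))
  meta <- df |>
    dplyr::distinct(dplyr::across(dplyr::all_of(c("sample_id", meta_cols))))
  assert_that(!anyDuplicated(meta$sample_id),
              "sample metadata must be constant within a sample")
  wide <- df |>
    dplyr::select("sample_id", "peak_id", "integral") |>
    tidyr::pivot_wider(names_from = "peak_id", values_from = "integral")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$sample_id
  if (anyNA(mat)) {
    if (zero_fill) mat[is.na(mat)] <- 0
    else stop("peak table has missing (sample, peak) combinations; ",
              "use zero_fill = TRUE to fill with 0", call. = FALSE)
  }
  meta <- meta[match(rownames(mat), meta$sample_id), ]
  peak_profiles(mat, meta)
}

#' Drop contaminant peaks by name
#'
#' Removes peaks arising from solvents or other contaminants (in the
#' original experiment: methanol and acetonitrile) from the peak axis.
#'
#' @param profiles A [peak_profiles()] object.
#' @param names Peak labels to remove; absent names trigger a warning.
#' @return Profiles on the reduced peak axis.
#' @export
remove_contaminants <- function(profiles, names) {
  pp <- as_peak_profiles(profiles)
  if (length(names) == 0) return(pp)
  absent <- setdiff(names, colnames(pp$values))
  if (length(absent) > 0) {
    warning("contaminant peaks not present: ", paste(absent, collapse = ", "))
  }
  keep <- setdiff(colnames(pp$values), names)
  assert_that(length(keep) > 0, "removing these peaks would empty the peak axis")
  peak_profiles(pp$values[, keep, drop = FALSE], pp$meta, delta = pp$delta)
}

#' Merge highly correlated peaks likely derived from one compound
#'
#' Peaks whose pairwise Pearson correlation across samples exceeds
#' `r_threshold` are grouped by single linkage (connected components of
#' the threshold graph) and each group is replaced by the sum of its
#' member peaks, mirroring the idea that multiple resonances of one
#' compound should be counted once.
#'
#' @param profiles A [peak_profiles()] object with >= 3 samples.
#' @param r_threshold Correlation threshold (default 0.95; pairs must
#'   exceed it strictly).
#' @return List with `profiles` (collapsed axis) and `groups` (tibble
#'   `group`, `peak_id` listing multi-peak groups).
#' @export
collapse_correlated_peaks <- function(profiles, r_threshold = 0.95) {
  pp <- as_peak_profiles(profiles)
  assert_that(nrow(pp$values) >= 3, "need >= 3 samples to estimate correlations")
  C <- suppressWarnings(cor(pp$values))
  C[is.na(C)] <- 0
  adj <- (C > r_threshold)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  peaks <- colnames(pp$values)
  new_cols <- tapply(peaks, comp, function(members) members, simplify = FALSE)
  mat <- vapply(new_cols, function(members) {
    rowSums(pp$values[, members, drop = FALSE])
  }, numeric(nrow(pp$values)))
  colnames(mat) <- vapply(new_cols, function(m) paste(m, collapse = "+"), "")
  # preserve original axis order by first member
  ord <- order(vapply(new_cols, function(m) match(m[1], peaks), 0L))
  mat <- mat[, ord, drop = FALSE]
  groups <- dplyr::bind_rows(lapply(seq_along(new_cols), function(k) {
    m <- new_cols[[k]]
    if (length(m) < 2) return(NULL)
    tibble::tibble(group = paste(m, collapse = "+"), peak_id = m)
  }))
  if (nrow(groups) == 0) {
    groups <- tibble::tibble(group = character(), peak_id = character())
  }
  list(profiles = peak_profiles(mat, pp$meta, delta = pp$delta),
       groups = groups)
}

#' Net change between two peak profiles
#'
#' Element-wise difference `after - before` on an identical peak axis;
#' positive values indicate net production of a compound during growth,
#' negative values net consumption.
#'
#' @param after,before Named numeric vectors (or single-sample profile
#'   rows) on the same peak axis.
#' @return Named numeric delta vector.
#' @export
net_change <- function(after, before) {
  after <- drop(as.matrix(after)); before <- drop(as.matrix(before))
  assert_that(!is.null(names(after)) && identical(names(after), names(before)),
              "profiles must share an identical peak axis")
  after - before
}

#' Metabolic-footprint deltas of single-species filtrates vs base medium
#'
#' For every single-species filtrate sample the mean base-medium profile
#' is subtracted, giving the species' net consumption/production
#' footprint.
#'
#' @param profiles A [peak_profiles()] object whose `lineage` metadata
#'   marks base-medium samples as `"base"` and single-species filtrates by
#'   the species label (pair filtrates, containing `">"`, are ignored).
#' @return A delta [peak_profiles()] object.
#' @export
footprint_deltas <- function(profiles) {
  pp <- as_peak_profiles(profiles)
  assert_that("lineage" %in% names(pp$meta), "profiles need lineage metadata")
  base_rows <- which(pp$meta$lineage == "base")
  assert_that(length(base_rows) >= 1, "no base-medium samples found")
  base_mean <- colMeans(pp$values[base_rows, , drop = FALSE])
  single <- which(pp$meta$lineage != "base" & !grepl(">", pp$meta$lineage))
  assert_that(length(single) >= 1, "no single-species filtrate samples found")
  d <- sweep(pp$values[single, , drop = FALSE], 2, base_mean)
  peak_profiles(d, pp$meta[single, ], delta = TRUE)
}

#' Principal components of unscaled (covariance) variation
#'
#' Centered but not variance-scaled PCA, so compounds with larger absolute
#' concentration changes dominate, with a deterministic sign convention:
#' in each component the largest-magnitude loading is positive.
#'
#' @param deltas A delta [peak_profiles()] object or numeric matrix
#'   (samples x peaks).
#' @param center Center columns before decomposition (default `TRUE`).
#' @return Object of class `pca_unscaled`: `loadings`, `scores`,
#'   `eigenvalues`, `variance_fraction`, `center`.
#' @export
pca_unscaled <- function(deltas, center = TRUE) {
  mat <- if (inherits(deltas, "peak_profiles")) deltas$values else as.matrix(deltas)
  assert_that(nrow(mat) >= 2 && ncol(mat) >= 2, "need >= 2 samples and >= 2 peaks")
  pc <- prcomp(mat, center = center, scale. = FALSE)
  for (j in seq_len(ncol(pc$rotation))) {
    i0 <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i0, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ev <- pc$sdev^2
  structure(list(loadings = pc$rotation, scores = pc$x, eigenvalues = ev,
                 variance_fraction = ev / sum(ev),
                 center = if (isTRUE(center)) pc$center else rep(0, ncol(mat))),
            class = "pca_unscaled")
}

#' @export
print.pca_unscaled <- function(x, ...) {
  k <- min(4, length(x$eigenvalues))
  cat("<pca_unscaled>", nrow(x$scores), "samples,",
      length(x$eigenvalues), "components\n")
  cat("  variance fractions:",
      paste(sprintf("PC%d=%.1f%%", seq_len(k), 100 * x$variance_fraction[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}

# Mean Euclidean distance between two groups of profile rows, averaged
# over all cross pairs.
mean_cross_distance <- function(a, b) {
  mean(vapply(seq_len(nrow(a)), function(i) {
    sqrt(colSums((t(b) - a[i, ])^2))
  }, numeric(nrow(b))))
}

profile_matrix_by_species <- function(x) {
  if (inherits(x, "peak_profiles")) {
    list(mat = x$values, species = x$meta$species)
  } else {
    m <- as.matrix(x)
    assert_that(!is.null(rownames(m)), "matrix rows must be named by species")
    list(mat = m, species = rownames(m))
  }
}

#' Amount of evolution: mean footprint distance from ancestral profiles
#'
#' Mean over species of the Euclidean distance between that species'
#' reference (ancestral) and evolved delta profiles; with replicate
#' profiles the mean over all cross pairs is taken per species.
#'
#' @param ancestral,evolved Delta [peak_profiles()] objects (with
#'   `species` metadata) or matrices with species rownames; both sides
#'   must cover the same species set.
#' @return Non-negative scalar.
#' @export
evolution_distance <- function(ancestral, evolved) {
  a <- profile_matrix_by_species(ancestral)
  e <- profile_matrix_by_species(evolved)
  sp <- sort(unique(a$species))
  assert_that(setequal(sp, unique(e$species)),
              "ancestral and evolved must cover the same species")
  mean(vapply(sp, function(s) {
    mean_cross_distance(a$mat[a$species == s, , drop = FALSE],
                        e$mat[e$species == s, , drop = FALSE])
  }, numeric(1)))
}

#' Amount of divergence: mean between-species footprint distance
#'
#' Mean over all unordered species pairs of the Euclidean distance between
#' their delta profiles within one treatment; with replicates the mean
#' over cross pairs is taken per species pair.
#'
#' @param profiles Delta [peak_profiles()] (with `species` metadata) or a
#'   matrix with species rownames; >= 2 species required.
#' @return Non-negative scalar.
#' @export
divergence_distance <- function(profiles) {
  p <- profile_matrix_by_species(profiles)
  sp <- sort(unique(p$species))
  assert_that(length(sp) >= 2, "divergence needs >= 2 species")
  pairs <- combn(sp, 2)
  mean(vapply(seq_len(ncol(pairs)), function(k) {
    mean_cross_distance(p$mat[p$species == pairs[1, k], , drop = FALSE],
                        p$mat[p$species == pairs[2, k], , drop = FALSE])
  }, numeric(1)))
}
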