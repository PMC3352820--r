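long_table <- function(mat, species = NA, treatment = NA, lineage = "base") {
  n <- nrow(mat)
  tidyr::expand_grid(i = seq_len(n), peak_id = colnames(mat)) |>
    dplyr::mutate(sample_id = sprintf("s%d", .data$i),
                  integral = mat[cbind(.data$i, match(.data$peak_id, colnames(mat)))],
                  species = rep_len(species, dplyr::n()),
                  treatment = rep_len(treatment, dplyr::n()),
                  lineage = rep_len(lineage, dplyr::n())) |>
    dplyr::select(-"i")
}

test_that("peak tables load, validate, and round-trip", {
  mat <- matrix(c(1, 2, 3, 4, 5, 6), 2, byrow = TRUE,
                dimnames = list(NULL, c("p1", "p2", "p3")))
  pp <- load_peak_table(long_table(mat))
  expect_equal(dim(pp), c(2, 3))
  expect_equal(unname(pp$values["s1", ]), c(1, 2, 3))

  dup <- dplyr::bind_rows(long_table(mat), long_table(mat)[1, ])
  expect_error(load_peak_table(dup), "duplicate")

  incomplete <- long_table(mat)[-1, ]
  expect_error(load_peak_table(incomplete), "missing")
  filled <- load_peak_table(incomplete, zero_fill = TRUE)
  expect_equal(unname(filled$values["s1", "p1"]), 0)

  # generator-written table round-trips through CSV
  cfg <- make_default_community(2, 4, seed = 1)
  tbl <- simulate_peak_table(list(ancestral = cfg), n_rep = 2, pairs = FALSE,
                             seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tbl, path)
  pp2 <- load_peak_table(path)
  expect_equal(nrow(pp2$values), dplyr::n_distinct(tbl$sample_id))
  expect_equal(sort(colnames(pp2$values)), sort(unique(tbl$peak_id)))
})

test_that("contaminant removal shrinks the peak axis and warns on absences", {
  mat <- matrix(runif(5 * 43), 5,
                dimnames = list(NULL, sprintf("pk%02d", 1:43)))
  pp <- peak_profiles(mat, tibble::tibble(sample_id = sprintf("s%d", 1:5)))
  out <- remove_contaminants(pp, c("pk01", "pk02"))
  expect_equal(ncol(out$values), 41)
  expect_identical(remove_contaminants(pp, character(0)), pp)
  expect_warning(remove_contaminants(pp, c("pk03", "nope")), "not present")
  expect_error(suppressWarnings(remove_contaminants(out, colnames(out$values))),
               "empty")
})

test_that("correlated peaks collapse by single linkage into summed groups", {
  set.seed(1)
  base <- rnorm(10)
  mat <- cbind(a = base, b = 2 * base, c = rnorm(10), d = rnorm(10))
  pp <- peak_profiles(mat - min(mat),
                      tibble::tibble(sample_id = sprintf("s%d", 1:10)))
  out <- collapse_correlated_peaks(pp)
  expect_equal(ncol(out$profiles$values), 3)
  expect_true("a+b" %in% colnames(out$profiles$values))
  expect_equal(out$profiles$values[, "a+b"],
               pp$values[, "a"] + pp$values[, "b"])
  expect_equal(unique(out$groups$group), "a+b")

  # no pair above the threshold: identity axis
  out2 <- collapse_correlated_peaks(pp, r_threshold = 1.01)
  expect_equal(colnames(out2$profiles$values), colnames(mat))

  # planted 3-peak group is found exactly
  set.seed(2)
  sig <- runif(12, 1, 2)
  mat3 <- cbind(x1 = sig, x2 = 3 * sig, x3 = 0.5 * sig,
                y = runif(12), z = runif(12))
  pp3 <- peak_profiles(mat3, tibble::tibble(sample_id = sprintf("s%d", 1:12)))
  out3 <- collapse_correlated_peaks(pp3)
  expect_setequal(out3$groups$peak_id, c("x1", "x2", "x3"))

  expect_error(collapse_correlated_peaks(
    peak_profiles(pp$values[1:2, ], tibble::tibble(sample_id = c("s1", "s2")))),
    ">= 3 samples")
})

test_that("net change subtracts profiles with production positive", {
  expect_equal(net_change(c(p1 = 1, p2 = 3), c(p1 = 2, p2 = 1)),
               c(p1 = -1, p2 = 2))
  expect_equal(net_change(c(p1 = 5), c(p1 = 5)), c(p1 = 0))
  expect_error(net_change(c(a = 1), c(b = 1)), "identical peak axis")

  # generator closed form: used-tea delta equals P_row - U_row * medium
  cfg <- make_default_community(3, 8, seed = 3)
  used <- simulate_used_tea(cfg, "B")
  expect_equal(net_change(used, cfg$base_medium),
               cfg$P["B", ] - cfg$U["B", ] * cfg$base_medium,
               tolerance = 1e-12)
})

test_that("unscaled PCA preserves variance and finds planted directions", {
  set.seed(4)
  direction <- c(3, 4, 0, 0) / 5
  scores_true <- rnorm(20, 0, 2)
  mat <- outer(scores_true, direction) +
    matrix(rnorm(80, 0, 1e-8), 20)
  colnames(mat) <- sprintf("p%d", 1:4)
  pca <- pca_unscaled(mat)
  expect_gt(abs(sum(pca$loadings[, 1] * direction)), 0.999)

  # eigenvalue sum equals total (unscaled) variance
  expect_equal(sum(pca$eigenvalues), sum(apply(mat, 2, var)),
               tolerance = 1e-8)

  # reconstruction from all components returns the centered input
  recon <- pca$scores %*% t(pca$loadings)
  centered <- sweep(mat, 2, pca$center)
  expect_equal(recon, centered, tolerance = 1e-8, ignore_attr = TRUE)

  # sign convention: dominant loading positive, deterministic across calls
  expect_gt(pca$loadings[which.max(abs(pca$loadings[, 1])), 1], 0)
  expect_identical(pca$loadings, pca_unscaled(mat)$loadings)

  # isotropic square: equal eigenvalues
  sq <- matrix(c(1, 0, -1, 0, 0, 1, 0, -1), 4, 2,
               dimnames = list(NULL, c("u", "v")))
  expect_equal(diff(pca_unscaled(sq)$eigenvalues), 0, tolerance = 1e-12)
})

test_that("evolution and divergence distances reproduce hand cases", {
  anc <- matrix(c(0, 0, 1, 1), 2, byrow = TRUE,
                dimnames = list(c("A", "B"), c("p1", "p2")))
  evo <- matrix(c(3, 4, 1, 1), 2, byrow = TRUE,
                dimnames = list(c("A", "B"), c("p1", "p2")))
  expect_equal(evolution_distance(anc, evo), 2.5)
  expect_equal(evolution_distance(anc, anc), 0)

  tri <- matrix(c(0, 0, 3, 0, 0, 4), 3, byrow = TRUE,
                dimnames = list(c("A", "B", "C"), c("p1", "p2")))
  expect_equal(divergence_distance(tri), 4)
  expect_equal(divergence_distance(tri + 10), 4) # translation invariance
  expect_equal(divergence_distance(matrix(1, 3, 2,
                                          dimnames = list(c("A", "B", "C"),
                                                          c("p1", "p2")))), 0)
  expect_error(divergence_distance(tri[1, , drop = FALSE]), ">= 2 species")
  expect_error(evolution_distance(anc, evo[1, , drop = FALSE]),
               "same species")
})

test_that("footprint deltas subtract the mean base-medium profile", {
  cfg <- tiny_config(U = matrix(c(0.5, 0.2), 2, 3),
                     P = matrix(0.1, 2, 3), noise_peak = 0)
  tbl <- simulate_peak_table(list(ancestral = cfg), n_rep = 2, pairs = FALSE,
                             seed = 5)
  deltas <- footprint_deltas(load_peak_table(tbl))
  expect_true(deltas$delta)
  expect_equal(nrow(deltas$values), 4) # 2 species x 2 reps
  td <- truth_delta_matrix(cfg)
  for (sp in c("A", "B")) {
    rows <- deltas$meta$species == sp
    expect_equal(colMeans(deltas$values[rows, , drop = FALSE]),
                 td[sp, ], tolerance = 1e-10)
  }
})
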