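test_that("delta statistics telescope to machine precision", {
  set.seed(1)
  peaks <- sprintf("p%d", 1:10)
  base <- setNames(runif(10), peaks)
  f1 <- setNames(runif(10), peaks)
  f2 <- setNames(runif(10), peaks)
  d01 <- delta_01(f1, base)
  d12 <- delta_12(f2, f1)
  expect_equal(d01 + d12, f2 - base, tolerance = 1e-15)
  expect_equal(delta_01(base, base), setNames(rep(0, 10), peaks))

  # generator truth: single-species delta_01 is P_row - U_row * base
  cfg <- make_default_community(3, 6, seed = 2)
  f <- simulate_used_tea(cfg, "C")
  expect_equal(delta_01(f, cfg$base_medium),
               cfg$P["C", ] - cfg$U["C", ] * cfg$base_medium,
               tolerance = 1e-12)
})

test_that("cross-feed records apply the produced-compound filter and hand arithmetic", {
  evolved <- tibble::tibble(
    first_species = "A", second_species = "B", treatment = "polyculture",
    compound = c("c1", "c2"),
    delta01 = c(2, -0.5),   # c2 not produced by the evolved isolate
    delta12 = c(-3, 1))
  ancestral <- tibble::tibble(
    first_species = "A", second_species = "B",
    compound = c("c1", "c2"), delta01 = c(1, 0.2), delta12 = c(-1, 0.5))
  rec <- build_crossfeed_table(evolved, ancestral)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$compound, "c1")
  expect_equal(rec$x, 1)   # 2 - 1
  expect_equal(rec$y, -2)  # -3 - (-1)

  # missing ancestral counterpart: skipped with a warning
  evolved2 <- dplyr::mutate(evolved, second_species = "C")
  expect_warning(rec2 <- build_crossfeed_table(evolved2, ancestral),
                 "no ancestral counterpart")
  expect_equal(nrow(rec2), 0)
})

test_that("per-treatment correlations and the interaction model are exact on constructed data", {
  x <- c(-1, 0, 1, 2, -2, 0.5)
  records <- dplyr::bind_rows(
    tibble::tibble(first_species = "A", second_species = "B",
                   treatment = "monoculture", compound = sprintf("m%d", 1:6),
                   x = x, y = -1 * x),
    tibble::tibble(first_species = "A", second_species = "B",
                   treatment = "polyculture", compound = sprintf("p%d", 1:6),
                   x = x, y = -2 * x))
  cors <- correlation_by_treatment(records)
  expect_equal(cors$r[cors$treatment == "monoculture"], -1, tolerance = 1e-12)
  expect_equal(cors$r[cors$treatment == "polyculture"], -1, tolerance = 1e-12)

  mod <- interaction_model(records)
  expect_equal(mod$interaction$estimate, -1.0, tolerance = 1e-10)
  expect_equal(unname(mod$slopes["monoculture"]), -1, tolerance = 1e-10)
  expect_equal(unname(mod$slopes["polyculture"]), -2, tolerance = 1e-10)

  # identical slopes: zero interaction
  same <- dplyr::mutate(records, y = -1.5 * x + 0.2)
  expect_equal(interaction_model(same)$interaction$estimate, 0,
               tolerance = 1e-10)

  expect_error(interaction_model(dplyr::filter(records,
                                               treatment == "monoculture")),
               "both monoculture and polyculture")
  degenerate <- dplyr::mutate(records, x = 1)
  expect_error(correlation_by_treatment(degenerate), "zero variance")
})

test_that("a pooled single-slope null keeps the interaction term near zero", {
  set.seed(5)
  ok <- 0
  n_rep <- 30
  for (i in seq_len(n_rep)) {
    x <- rnorm(40)
    y <- -1.2 * x + rnorm(40, 0, 0.3)
    records <- tibble::tibble(
      first_species = "A", second_species = "B",
      treatment = rep(c("monoculture", "polyculture"), each = 20),
      compound = sprintf("c%d", 1:40), x = x, y = y)
    m <- interaction_model(records)
    ok <- ok + (abs(m$interaction$estimate) < 3 * m$interaction$se)
  }
  expect_gte(ok / n_rep, 0.8)
})

test_that("generator coupling produces negatively correlated production/consumption shifts", {
  cfg <- make_default_community(4, 12, seed = 9)
  configs <- list(
    ancestral = cfg,
    monoculture = evolve_isolates(cfg, "monoculture", 1),
    polyculture = evolve_isolates(cfg, "polyculture", 1))
  tbl <- simulate_peak_table(configs, n_rep = 2, pairs = TRUE, seed = 10)
  cfd <- microcosm:::crossfeed_deltas(load_peak_table(tbl))
  rec <- build_crossfeed_table(
    dplyr::filter(cfd, treatment != "ancestral"),
    dplyr::filter(cfd, treatment == "ancestral"))
  cors <- correlation_by_treatment(rec)
  expect_lt(cors$r[cors$treatment == "polyculture"], 0)
  mod <- interaction_model(rec)
  expect_lt(mod$interaction$estimate, 0)
})
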