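test_that("default community has overlapping consumption and valid invariants", {
  cfg <- make_default_community(4, 10, seed = 1)
  expect_true(any(colSums(cfg$U > 0) >= 2))
  expect_true(all(cfg$U >= 0 & cfg$U <= 1))
  expect_true(all(cfg$P >= 0))
  expect_true(all(cfg$base_medium >= 0))
  expect_true(all(cfg$r > 0) && all(cfg$K > 0))

  cfg2 <- make_default_community(2, 2, seed = 7)
  expect_true(all(cfg2$U >= 0 & cfg2$U <= 1))
  expect_identical(make_default_community(3, 6, seed = 11),
                   make_default_community(3, 6, seed = 11))
  expect_error(make_default_community(1, 5), "n_species")
  expect_error(make_default_community(4, 0), "n_compounds")
})

test_that("evolution with zero effect size is the identity for all treatments", {
  cfg <- make_default_community(4, 10, seed = 2)
  for (tr in c("ancestral", "monoculture", "polyculture")) {
    expect_identical(evolve_isolates(cfg, tr, effect_size = 0), cfg)
  }
  expect_error(evolve_isolates(cfg, "coculture"), "unknown treatment")
})

test_that("polyculture pushes consumption rows apart, monoculture pulls together", {
  for (seed in 1:5) {
    cfg <- make_default_community(4, 12, seed = seed)
    d0 <- mean(dist(cfg$U))
    d_poly <- mean(dist(evolve_isolates(cfg, "polyculture", 1)$U))
    d_mono <- mean(dist(evolve_isolates(cfg, "monoculture", 1)$U))
    expect_gt(d_poly, d0)
    expect_lte(d_mono, d0)
  }
})

test_that("used-tea composition follows medium*(1-U)+P and stays non-negative", {
  cfg0 <- tiny_config(U = matrix(0, 2, 3), P = matrix(0, 2, 3))
  expect_equal(simulate_used_tea(cfg0, "A"), cfg0$base_medium)

  cfg1 <- tiny_config(U = matrix(1, 2, 3),
                      P = matrix(c(0.2, 0.4, 0.6), 2, 3, byrow = TRUE))
  expect_equal(unname(simulate_used_tea(cfg1, "B")), c(0.2, 0.4, 0.6))

  # chaining two species equals applying the formula twice
  cfg <- make_default_community(3, 8, seed = 3)
  once <- simulate_used_tea(cfg, "A")
  twice <- simulate_used_tea(cfg, "B", medium = once)
  by_hand <- (cfg$base_medium * (1 - cfg$U["A", ]) + cfg$P["A", ]) *
    (1 - cfg$U["B", ]) + cfg$P["B", ]
  expect_equal(twice, by_hand, tolerance = 1e-12)

  # non-negativity on random configurations
  for (seed in 1:10) {
    cfgr <- make_default_community(3, 6, seed = seed)
    for (sp in cfgr$species_ids) {
      expect_true(all(simulate_used_tea(cfgr, sp) >= 0))
    }
  }
  expect_error(simulate_used_tea(cfg, "Z"), "not in config")
})

test_that("growth curves follow logistic dynamics with an exponential limit", {
  cfg <- tiny_config(r = c(2, 3), K = c(1e18, 1e18), noise_od = 0)
  cfg$blank_od <- 0
  rows <- simulate_growth_curve(cfg, "A", "ancestral", 1,
                                times = c(0, 24, 48), n0 = 1e6)
  meas <- rows[!rows$is_control, ]
  log2n <- (cfg$cal_intercepts["A"] + cfg$cal_slope * meas$od600) / log10(2)
  slope <- diff(log2n) / diff(meas$time_h / 24)
  expect_equal(unname(slope), c(2, 2), tolerance = 1e-9)

  # medium without consumable resource -> flat at the inoculum density
  flat <- simulate_growth_curve(cfg, "A", "ancestral", 1,
                                medium = rep(0, 3), times = c(0, 24, 48),
                                n0 = 1e6)
  expect_equal(diff(flat$od600[!flat$is_control]), c(0, 0), tolerance = 1e-12)

  # determinism: identical seed gives a bitwise-identical table
  cfg2 <- make_default_community(3, 6, seed = 4)
  a <- simulate_growth_curve(cfg2, "A", "ancestral", 1, seed = 99)
  b <- simulate_growth_curve(cfg2, "A", "ancestral", 1, seed = 99)
  expect_identical(a, b)
})

test_that("serial transfers stay at carrying capacity without noise", {
  cfg <- tiny_config(K = c(4e8, 4e8))
  log0 <- simulate_serial_transfer(cfg, n_transfers = 5, dilution = 20,
                                   noise = 0, seed = 1)
  expect_true(all(log0$density_per_ml == 4e8))
  expect_identical(simulate_serial_transfer(cfg, 5, 20, seed = 3),
                   simulate_serial_transfer(cfg, 5, 20, seed = 3))
})

test_that("null datasets are deterministic and free of species/treatment structure", {
  cfg <- make_default_community(4, 10, seed = 5)
  ds <- simulate_null_dataset(cfg, seed = 1, tables = "peaks",
                              n_rep_peaks = 1, pairs = FALSE)
  ds2 <- simulate_null_dataset(cfg, seed = 1, tables = "peaks",
                               n_rep_peaks = 1, pairs = FALSE)
  expect_identical(ds$peaks, ds2$peaks)
  # evolved parameter sets are identical across treatments
  expect_identical(ds$truth$configs$ancestral$U,
                   ds$truth$configs$polyculture$U)
  expect_identical(ds$truth$configs$monoculture$r,
                   ds$truth$configs$polyculture$r)
  # all species share one expected footprint
  td <- truth_delta_matrix(ds$truth$configs$ancestral)
  expect_lt(max(dist(td)), 1e-12)
})

test_that("written datasets round-trip through CSV and the manifest records truth", {
  cfg <- make_default_community(2, 4, seed = 6)
  ds <- simulate_dataset(cfg, effect_size = 0.5, seed = 2,
                         n_rep_growth = 2, n_rep_peaks = 2,
                         times = c(0, 24, 48))
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)
  expect_true(all(file.exists(paths)))
  back <- readr::read_csv(paths[["peaks"]], show_col_types = FALSE)
  expect_equal(nrow(back), nrow(ds$peaks))
  expect_equal(back$integral, ds$peaks$integral, tolerance = 1e-12)
  man <- yaml::read_yaml(paths[["manifest"]])
  expect_equal(man$seed, 2)
  expect_equal(man$effect_size, 0.5)
  expect_equal(unlist(man$species), cfg$species_ids)
})
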