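# small shared fixture: cheap map/founders/architecture for scheme tests
scheme_fixture <- function(eps = 0, seed = 50) {
  map <- build_map(4, rep(100, 4), 200, 8, 12, seed = seed)
  fnd <- simulate_founders(map, 120, seed = seed + 1)
  arch <- sample_architecture(map, fnd, epistasis_ratio = eps,
                              seed = seed + 2)
  list(map = map, fnd = fnd, arch = arch)
}

small_burnin <- function(...) {
  burnin_config(n_crosses = 20, progeny_per_cross = 20, ...)
}

test_that("scheme configuration enforces the budget and parent accounting", {
  for (sz in c(25, 50, 100, 200)) {
    cfg <- scheme_config("budget", progeny_per_cross = sz)
    expect_equal(cfg$n_crosses * cfg$progeny_per_cross, 4000)
    expect_equal(cfg$n_crosses, 4000 / sz)
    expect_equal(cfg$n_test_selected + cfg$n_shelf_selected, cfg$n_parents)
  }
  expect_equal(scheme_config("theoretical", progeny_per_cross = 200)$n_crosses, 40)
  expect_error(scheme_config("budget", progeny_per_cross = 33),
               "does not divide")
  expect_error(scheme_config("theoretical", n_test_selected = 10),
               "must equal n_parents")
})

test_that("burn-in runs the configured horizon and returns calibrated baselines", {
  fx <- scheme_fixture()
  bb <- run_burnin(fx$fnd, fx$arch, small_burnin(), seed = 60)
  expect_equal(bb$years, 15)
  expect_equal(n_ind(bb$parents), 40)
  expect_equal(bb$baseline$cycle, 0)
  expect_equal(bb$baseline$year, 0)
  expect_equal(bb$baseline$mean_G, bb$baseline$parents_mean_G)
  # near-inbred F6 lines
  expect_lt(mean(heterozygosity(bb$parents)), 0.15)
})

test_that("phenotypic burn-in selection yields positive gain in nearly all replicates", {
  fx <- scheme_fixture()
  cfgsel <- small_burnin(select_on = rep("phenotype", 3))
  gains <- vapply(1:12, function(s) {
    run_burnin(fx$fnd, fx$arch, cfgsel, seed = 600 + s)$baseline$mean_G
  }, 0)
  expect_gte(mean(gains > 0), 0.95)
})

test_that("unselected burn-in drifts around the founder mean", {
  fx <- scheme_fixture()
  cfg0 <- small_burnin(keep_fractions = c(1, 1, 1),
                       select_on = rep("random", 3), n_cycles = 1,
                       n_parents = 400)  # parents = census: no selection
  d <- vapply(1:10, function(s) {
    run_burnin(fx$fnd, fx$arch, cfg0, seed = 700 + s)$baseline$mean_G
  }, 0)
  expect_lt(abs(mean(d)), 4 * sd(d) / sqrt(length(d)) + 0.05)
})

test_that("one GS cycle performs the full test-and-shelf accounting", {
  fx <- scheme_fixture()
  bb <- run_burnin(fx$fnd, fx$arch, small_burnin(), seed = 61)
  cfg <- scheme_config("theoretical", progeny_per_cross = 50,
                       n_cycles = 1, n_train_frac = 0.3)
  set.seed(62)
  step <- suppressWarnings(
    run_gs_cycle(list(parents = bb$parents, cycle = 0L), fx$arch, cfg))
  expect_equal(step$record$n_F2, 40 * 50)
  expect_equal(n_ind(step$state$parents), 40)
  expect_equal(step$state$parents$generation, "F6")
  expect_equal(step$record$cycle, 1)
  expect_equal(step$record$year, 5)
  expect_true(is.na(step$record$accuracy) ||
              abs(step$record$accuracy) <= 1)
  expect_true(all(step$record[c("Va", "Vaa")] >= 0))
})

test_that("budget context holds the F2 census at the cap for every progeny size", {
  fx <- scheme_fixture()
  bb <- run_burnin(fx$fnd, fx$arch, small_burnin(), seed = 63)
  for (sz in c(25, 50, 100, 200)) {
    cfg <- scheme_config("budget", progeny_per_cross = sz, n_cycles = 1,
                         n_train_frac = 0.2)
    rec <- suppressWarnings(
      run_program(bb$parents, fx$arch, cfg, seed = 64, baseline = bb$baseline))
    expect_equal(rec$n_F2[2], 4000)
  }
})

test_that("programs are reproducible and respect the cycle count", {
  fx <- scheme_fixture()
  bb <- run_burnin(fx$fnd, fx$arch, small_burnin(), seed = 65)
  cfg <- scheme_config("theoretical", progeny_per_cross = 25, n_cycles = 2,
                       n_train_frac = 0.3)
  r1 <- suppressWarnings(run_program(bb$parents, fx$arch, cfg, seed = 66,
                                     baseline = bb$baseline))
  r2 <- suppressWarnings(run_program(bb$parents, fx$arch, cfg, seed = 66,
                                     baseline = bb$baseline))
  expect_identical(r1, r2)
  expect_equal(r1$cycle, 0:2)
  expect_equal(r1$year, c(0, 5, 10))

  r0 <- run_program(bb$parents, fx$arch,
                    scheme_config("theoretical", progeny_per_cross = 25,
                                  n_cycles = 0), seed = 67,
                    baseline = bb$baseline)
  expect_equal(nrow(r0), 1)
  expect_equal(r0$cycle, 0)
})

test_that("selection on pure noise gives no systematic response", {
  fx <- scheme_fixture()
  bb <- run_burnin(fx$fnd, fx$arch, small_burnin(), seed = 68)
  arch0 <- fx$arch
  arch0$error_variance <- 1e6  # heritability ~ 0
  cfg <- scheme_config("theoretical", progeny_per_cross = 25, n_cycles = 1,
                       n_train_frac = 0.3)
  d <- vapply(1:8, function(s) {
    rec <- suppressWarnings(run_program(bb$parents, arch0, cfg,
                                        seed = 800 + s,
                                        baseline = bb$baseline))
    rec$parents_mean_G[2] - rec$parents_mean_G[1]
  }, 0)
  expect_lt(abs(mean(d)), 4 * sd(d) / sqrt(length(d)) + 0.05)
})

test_that("undersized states and test groups are rejected", {
  fx <- scheme_fixture()
  bb <- run_burnin(fx$fnd, fx$arch, small_burnin(), seed = 69)
  cfg <- scheme_config("theoretical", progeny_per_cross = 25, n_cycles = 1)
  expect_error(run_gs_cycle(list(parents = fx$fnd, cycle = 0L), fx$arch, cfg),
               "n_parents")
  tiny <- scheme_config("theoretical", progeny_per_cross = 2, n_cycles = 1,
                        min_test_for_reml = 30)
  set.seed(70)
  expect_error(run_gs_cycle(list(parents = bb$parents, cycle = 0L),
                            fx$arch, tiny),
               "smaller than the REML minimum")
})
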