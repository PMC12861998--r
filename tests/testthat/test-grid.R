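test_that("the full factorial grid resolves cross counts per context", {
  grid <- scenario_grid(master_seed = 1, scale = "reduced")
  scen <- expand_scenarios(grid)
  expect_equal(nrow(scen), 2 * 4 * 3)
  budget <- scen[scen$context == "budget", ]
  expect_equal(budget$n_crosses[order(budget$progeny_size)][c(1, 4, 7, 10)],
               c(160, 80, 40, 20))
  expect_true(all(scen$n_crosses[scen$context == "theoretical"] == 40))

  empty <- scenario_grid(progeny_sizes = integer(0), scale = "reduced")
  expect_equal(nrow(expand_scenarios(empty)), 0)

  odd <- scenario_grid(progeny_sizes = 33, scale = "reduced")
  expect_error(expand_scenarios(odd), "do not divide")
})

test_that("replicate seed streams are distinct and reproducible", {
  s1 <- epigain:::derive_seeds(99, 50)
  s2 <- epigain:::derive_seeds(99, 50)
  expect_identical(s1, s2)
  expect_equal(anyDuplicated(s1), 0)
  expect_false(identical(s1, epigain:::derive_seeds(100, 50)))
})

tiny_grid <- function(master_seed = 5, n_replicates = 2, ...) {
  scenario_grid(contexts = "theoretical", progeny_sizes = 25,
                epistasis_ratios = 0, n_replicates = n_replicates,
                master_seed = master_seed, scale = "reduced", n_cycles = 3,
                n_founders = 80L, n_chromosomes = 2L,
                chr_lengths_cM = rep(100, 2), n_loci = 80L,
                n_qtn_per_chr = 5L, n_snp_per_chr = 8L,
                burnin = burnin_config(n_crosses = 15, progeny_per_cross = 15),
                ...)
}

test_that("a reduced grid run emits the expected record table", {
  grid <- tiny_grid()
  rec <- suppressWarnings(run_scenario_grid(grid))
  expect_equal(nrow(rec), 2 * 4)  # 2 replicates x (baseline + 3 cycles)
  expect_setequal(unique(rec$cycle), 0:3)
  expect_true(all(rec$scenario_id == "theoretical_s25_e0"))
  expect_true(all(c("mean_G", "Va", "Vaa", "accuracy", "parents_mean_G",
                    "seed") %in% names(rec)))
  rec2 <- suppressWarnings(run_scenario_grid(grid))
  expect_identical(rec$mean_G, rec2$mean_G)  # order- and rerun-invariant
})

test_that("interrupted grid runs resume to the same table", {
  grid <- tiny_grid(master_seed = 6)
  out_full <- tempfile(fileext = ".csv")
  full <- suppressWarnings(run_scenario_grid(grid, out = out_full))
  expect_true(file.exists(paste0(out_full, ".manifest.txt")))

  # simulate an interruption: keep only replicate 1 on disk, then resume
  out_part <- tempfile(fileext = ".csv")
  part <- full[full$replicate == 1, ]
  write.csv(part, out_part, row.names = FALSE)
  resumed <- suppressWarnings(run_scenario_grid(grid, out = out_part,
                                                resume = TRUE))
  got <- read.csv(out_part)
  want <- read.csv(out_full)
  key <- function(d) d[order(d$replicate, d$cycle),
                       c("replicate", "cycle", "mean_G", "parents_mean_G")]
  expect_equal(key(got), key(want), ignore_attr = TRUE)
  unlink(c(out_full, out_part, paste0(out_full, ".manifest.txt"),
           paste0(out_part, ".manifest.txt")))
})

test_that("program responses collapse records to per-replicate outcomes", {
  grid <- tiny_grid(master_seed = 7)
  rec <- suppressWarnings(run_scenario_grid(grid))
  resp <- program_responses(rec)
  expect_equal(nrow(resp), 2)
  sub <- rec[rec$replicate == 1, ]
  expect_equal(resp$response[resp$replicate == 1],
               sub$parents_mean_G[sub$cycle == 3] -
                 sub$mean_G[sub$cycle == 0])
  expect_equal(resp$annualized_pct[resp$replicate == 1],
               (100 / 15) * (sub$parents_mean_G[sub$cycle == 3] -
                             sub$mean_G[sub$cycle == 0]) /
                 abs(sub$mean_G[sub$cycle == 0]))
  smry <- summarize_records(rec)
  expect_true(all(smry$rel_mean_G[smry$cycle == 0] == 1))
})

test_that("plain-text configurations map onto scenario grids", {
  cfg <- tempfile(fileext = ".cfg")
  writeLines(c("# desk-scale example",
               "contexts = budget",
               "progeny_sizes = 25, 50",
               "epistasis_ratios = 0, 0.5",
               "n_replicates = 3",
               "master_seed = 11",
               "scale: reduced",
               "n_cycles = 4"), cfg)
  grid <- read_scenario_config(cfg)
  expect_s3_class(grid, "scenario_grid")
  expect_equal(grid$contexts, "budget")
  expect_equal(grid$progeny_sizes, c(25L, 50L))
  expect_equal(grid$epistasis_ratios, c(0, 0.5))
  expect_equal(grid$n_replicates, 3L)
  expect_equal(grid$n_cycles, 4L)
  expect_equal(nrow(expand_scenarios(grid)), 4)
  writeLines("progeny sizes 25", cfg)
  expect_error(read_scenario_config(cfg), "cannot parse")
  unlink(cfg)
})
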