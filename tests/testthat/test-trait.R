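test_that("calibration normalizes founder genetic variance and epistatic ratio", {
  map <- tiny_map(2, 100, 60, 6, 8, seed = 2)
  fnd <- simulate_founders(map, 150, seed = 3)
  for (ratio in c(0, 0.5, 1.0)) {
    arch <- sample_architecture(map, fnd, epistasis_ratio = ratio, seed = 4)
    g <- genetic_value(fnd, arch)
    expect_equal(mean(g$G), 0, tolerance = 1e-6)
    expect_equal(var(g$G), 1, tolerance = 1e-6)
    if (ratio == 0) {
      expect_equal(nrow(arch$epistatic_pairs), 0)
      expect_true(all(g$epistatic == g$epistatic[1]))
    } else {
      realized <- var(g$epistatic) / var(g$additive)
      expect_true(abs(realized / ratio - 1) < 0.01)
    }
  }
})

test_that("error variance solves the broad-sense heritability identity", {
  map <- tiny_map()
  fnd <- simulate_founders(map, 100, seed = 5)
  arch <- sample_architecture(map, fnd, epistasis_ratio = 0.5,
                              target_H2 = 0.63, seed = 6)
  expect_equal(arch$error_variance, (1 - 0.63) / 0.63, tolerance = 1e-12)
})

test_that("the genetic value is the stated bilinear form (hand case)", {
  hap <- matrix(1L, nrow = 2, ncol = 2)  # one individual, dosage (1, 1)
  pop <- pop_from_haps(hap)
  arch <- trait_architecture(qtn_loci = 1:2, additive_effects = c(1, 2),
                             epistatic_pairs = matrix(c(1L, 2L), 1),
                             epistatic_effects = 3,
                             dosage_centering = c(0, 0),
                             error_variance = 1)
  g <- genetic_value(pop, arch)
  expect_equal(g$G, 1 + 2 + 3)
  expect_equal(g$additive, 3)
  expect_equal(g$epistatic, 3)

  # all-zero scaled dosages sit at the origin of the bilinear form
  hap0 <- rbind(c(1L, 1L), c(0L, 0L))  # heterozygous: dosage (0, 0)
  g0 <- genetic_value(pop_from_haps(hap0), arch)
  expect_equal(g0$G, 0)
})

test_that("additive and epistatic components always sum to G exactly", {
  map <- tiny_map(2, 100, 50, 5, 5, seed = 8)
  fnd <- simulate_founders(map, 80, seed = 9)
  arch <- sample_architecture(map, fnd, epistasis_ratio = 1, seed = 10)
  prog <- make_crosses(fnd, random_pairs(fnd$ids, 10, 20, "F1"), seed = 11)
  g <- genetic_value(prog, arch)
  expect_equal(g$G, g$additive + g$epistatic)
})

test_that("phenotype noise has the calibrated variance and vanishes in the limit", {
  # many copies of one genotype: Y spread is pure error
  hap <- matrix(rep(c(1L, 0L), each = 1), nrow = 2, ncol = 4)
  hap <- hap[rep(1:2, 2e4), ]
  map <- build_map(1, 100, 4, 0, 0, seed = 1)
  pop <- haplo_pop(hap, map, ids = as.character(seq_len(2e4)))
  arch <- trait_architecture(qtn_loci = 1:2, additive_effects = c(1, 1),
                             error_variance = 2, intercept = 5)
  ph <- phenotype(pop, arch, seed = 12)
  expect_lt(abs(var(ph$Y) / 2 - 1), 0.02)
  expect_equal(mean(ph$Y), 5 + ph$G[1], tolerance = 0.05)

  arch$error_variance <- 1e-18
  ph0 <- phenotype(pop, arch, seed = 13)
  expect_equal(ph0$Y, 5 + ph0$G, tolerance = 1e-6)
})

test_that("founder heritability and regression slope recover the targets", {
  map <- tiny_map(3, 100, 90, 8, 10, seed = 14)
  fnd <- simulate_founders(map, 800, seed = 15)
  arch <- sample_architecture(map, fnd, epistasis_ratio = 0.5, seed = 16)
  ph <- phenotype(fnd, arch, seed = 17)
  H2 <- var(ph$G) / var(ph$Y)
  expect_gt(H2, 0.58)
  expect_lt(H2, 0.68)
  slope <- coef(lm(ph$Y ~ ph$G))[2]
  expect_equal(unname(slope), 1, tolerance = 0.1)
})

test_that("seed changes preserve the calibration targets", {
  map <- tiny_map(2, 100, 60, 6, 8, seed = 2)
  fnd <- simulate_founders(map, 150, seed = 3)
  for (s in c(21, 22)) {
    arch <- sample_architecture(map, fnd, epistasis_ratio = 0.5, seed = s)
    g <- genetic_value(fnd, arch)
    expect_equal(var(g$G), 1, tolerance = 1e-8)
    expect_true(abs(var(g$epistatic) / var(g$additive) / 0.5 - 1) < 0.01)
  }
})

test_that("degenerate architectures are rejected", {
  map <- tiny_map(1, 100, 10, 1, 2)
  fnd <- simulate_founders(map, 30, seed = 30)
  expect_error(sample_architecture(map, fnd, epistasis_ratio = 0.5, seed = 1),
               "at least 2 QTNs")
  expect_error(trait_architecture(1:2, c(1, 1),
                                  epistatic_pairs = matrix(c(1L, 1L), 1),
                                  epistatic_effects = 1),
               "distinct")
  expect_error(trait_architecture(1:2, c(1, 1), error_variance = 0))
})

test_that("architecture audit tables round-trip", {
  map <- tiny_map(1, 100, 20, 4, 4, seed = 2)
  fnd <- simulate_founders(map, 40, seed = 2)
  arch <- sample_architecture(map, fnd, epistasis_ratio = 1, seed = 3)
  f <- tempfile(fileext = ".csv")
  write_architecture(arch, map, f)
  qt <- read.csv(f)
  expect_equal(nrow(qt), 4)
  expect_equal(qt$additive_effect, arch$additive_effects)
  pt <- read.csv(paste0(f, ".pairs"))
  expect_equal(nrow(pt), 2)
  unlink(c(f, paste0(f, ".pairs")))
})
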