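test_that("NR-REML agrees with a grid-search restricted likelihood and MME BLUPs", {
  k <- sim_kernels(60, 45, seed = 21)
  y <- sim_gblup_y(k$Ga, k$Gaa_norm, mu = 4, s_a = 1, s_aa = 0.6,
                   s_e = 0.5, seed = 22)
  fit <- fit_gblup(y, k$Ga, k$Gaa_norm)
  expect_true(fit$converged)

  kernels <- list(k$Ga, k$Gaa_norm)
  ll_fit <- reml_ll_oracle(y, kernels,
                           unname(fit$sigma[c("sigma_a2", "sigma_aa2",
                                              "sigma_e2")]))
  expect_equal(unname(ll_fit), fit$loglik, tolerance = 1e-6)
  best <- grid_reml(y, kernels, center = unname(fit$sigma))
  expect_gte(ll_fit + 1e-3, best$ll)

  mme <- mme_oracle(y, k$Ga, k$Gaa_norm,
                    sigma = c(fit$sigma[1], fit$sigma[2], NA, fit$sigma[3]))
  expect_lt(max(abs(fit$blup_a - mme$blup_a)), 1e-6)
  expect_lt(max(abs(fit$blup_aa - mme$blup_aa)), 1e-6)
  expect_equal(fit$mu, mme$beta[1], tolerance = 1e-6)
})

test_that("the balanced one-way special case matches the classical closed form", {
  g <- 12; n_per <- 6
  Z <- kronecker(diag(g), matrix(1, n_per, 1))
  Ka <- tcrossprod(Z)
  set.seed(23)
  y <- drop(Z %*% rnorm(g, 0, sqrt(2))) + rnorm(g * n_per, 0, 1)
  grp <- rep(seq_len(g), each = n_per)
  msb <- n_per * var(tapply(y, grp, mean))
  msw <- sum((y - ave(y, grp))^2) / (g * (n_per - 1))
  fit <- fit_gblup(y, Ka)
  expect_equal(unname(fit$sigma["sigma_e2"]), msw, tolerance = 1e-4)
  expect_equal(unname(fit$sigma["sigma_a2"]), (msb - msw) / n_per,
               tolerance = 1e-4)
})

test_that("REML is invariant to phenotype shifts up to the intercept", {
  k <- sim_kernels(40, 30, seed = 24)
  y <- sim_gblup_y(k$Ga, k$Gaa_norm, 0, 1, 0.5, 0.7, seed = 25)
  f0 <- fit_gblup(y, k$Ga, k$Gaa_norm)
  f1 <- fit_gblup(y + 100, k$Ga, k$Gaa_norm)
  expect_equal(f1$mu - f0$mu, 100, tolerance = 1e-5)
  expect_equal(f1$sigma, f0$sigma, tolerance = 1e-5)
  expect_equal(f1$blup_a, f0$blup_a, tolerance = 1e-5)
})

test_that("kernel rescaling is absorbed by the variance component", {
  # m < n so the additive kernel is singular and sigma_e is well identified
  k <- sim_kernels(60, 20, seed = 26)
  y <- sim_gblup_y(k$Ga, k$Gaa_norm, 1, 0.8, 0.4, 0.6, seed = 27)
  f1 <- fit_gblup(y, k$Ga, k$Gaa_norm)
  f2 <- fit_gblup(y, 4 * k$Ga, k$Gaa_norm)
  expect_equal(unname(4 * f2$sigma["sigma_a2"]),
               unname(f1$sigma["sigma_a2"]), tolerance = 1e-3)
  expect_equal(f1$blup_a, f2$blup_a, tolerance = 1e-4)
})

test_that("an absent second component shrinks to the boundary", {
  # two structurally unrelated kernels keep the components identifiable
  set.seed(28)
  n <- 150
  Ka <- tcrossprod(kronecker(diag(n / 5), matrix(1, 5, 1)))  # family blocks
  W <- matrix(rnorm(n * 40), n, 40)
  Kaa <- tcrossprod(W) / 40
  y <- sim_gblup_y(Ka, Kaa, 0, s_a = 1, s_aa = 1e-12, s_e = 0.5, seed = 29)
  fit <- suppressWarnings(fit_gblup(y, Ka, Kaa))
  expect_lt(unname(fit$sigma["sigma_aa2"]), 0.05 * var(y))
  # BLUP shrinkage follows the component
  expect_lt(sqrt(mean(fit$blup_aa^2)), 0.1 * sd(y))
})

test_that("fitted decomposition and accessors are coherent", {
  k <- sim_kernels(35, 25, seed = 30)
  y <- sim_gblup_y(k$Ga, k$Gaa_norm, 2, 1, 0.5, 0.5, seed = 31)
  fit <- fit_gblup(y, k$Ga, k$Gaa_norm)
  expect_equal(fitted(fit) + residuals(fit), y)
  expect_equal(fitted(fit), fit$mu + fit$blup_a + fit$blup_aa)
  expect_named(coef(fit), "(Intercept)")
  expect_s3_class(summary(fit), "summary.gblup")
  expect_true(all(fit$sigma >= 0))
  sims <- simulate(fit, nsim = 3, seed = 32)
  expect_equal(dim(sims), c(35, 3))
  expect_output(print(fit), "NR-REML")
})

test_that("projection reproduces fitted predictions and the prior mean", {
  k <- sim_kernels(30, 40, seed = 33)
  y <- sim_gblup_y(k$Ga, k$Gaa_norm, 1, 1, 0.6, 0.5, seed = 34)
  fit <- fit_gblup(y, k$Ga, k$Gaa_norm)

  # test-set self-projection returns the fitted BLUPs exactly
  self_proj <- project_gblup(fit, k$Ga, k$Gaa_norm)
  expect_equal(as.numeric(self_proj), fit$mu + fit$blup_a + fit$blup_aa,
               tolerance = 1e-6)

  # unrelated individuals fall back to the intercept
  zero <- project_gblup(fit, matrix(0, 30, 5), matrix(0, 30, 5))
  expect_equal(as.numeric(zero), rep(fit$mu, 5), tolerance = 1e-10)

  # the direct (no pseudo-inverse) path agrees with the pseudo-inverse path
  direct <- epigain:::project_gblup_direct(fit, k$Ga, k$Gaa_norm)
  expect_equal(as.numeric(direct), as.numeric(self_proj), tolerance = 1e-6)
})

test_that("kriging projection equals the joint conditional-mean oracle", {
  # union of 20 phenotyped and 8 unphenotyped individuals; kernels built on
  # the union, partitioned, model fitted on the phenotyped block
  set.seed(35)
  n_t <- 20; n_s <- 8
  G <- matrix(sample(c(-1L, 0L, 1L), (n_t + n_s) * 60, replace = TRUE),
              n_t + n_s, 60)
  G[n_t + 1, ] <- G[1, ]  # one shelf individual duplicates a test genotype
  M <- sweep(G, 2, colMeans(G))
  Ga <- additive_grm(M)
  Gaa <- epistatic_grm(Ga)$Gaa_norm
  ti <- seq_len(n_t); si <- n_t + seq_len(n_s)
  y <- sim_gblup_y(Ga[ti, ti], Gaa[ti, ti], 3, 1, 0.5, 0.4, seed = 36)
  fit <- fit_gblup(y, Ga[ti, ti], Gaa[ti, ti])
  proj <- project_gblup(fit, Ga[ti, si], Gaa[ti, si])

  # oracle: E[g_s | y] = Cov(g_s, y) V^{-1} (y - X beta) + mu on the union
  V <- fit$sigma[1] * Ga[ti, ti] + fit$sigma[2] * Gaa[ti, ti] +
    diag(fit$sigma[3], n_t)
  Csy <- fit$sigma[1] * t(Ga[ti, si]) + fit$sigma[2] * t(Gaa[ti, si])
  oracle <- fit$mu + drop(Csy %*% solve(V, y - fit$mu))
  expect_equal(as.numeric(proj), oracle, tolerance = 1e-6)

  # the duplicated genotype receives that test individual's prediction
  expect_equal(as.numeric(proj)[1],
               fit$mu + fit$blup_a[1] + fit$blup_aa[1], tolerance = 1e-6)

  expect_error(project_gblup(fit, Ga[ti, si]), "Kaa_cross")
})

test_that("non-finite or empty phenotypes are rejected", {
  k <- sim_kernels(10, 5, seed = 37)
  expect_error(fit_gblup(rep(1, 10), k$Ga, k$Gaa_norm), "no variance")
  expect_error(fit_gblup(rnorm(9), k$Ga, k$Gaa_norm))
})
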