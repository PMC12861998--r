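# Shared fixtures and independent oracles, all built in code.

tiny_map <- function(n_chr = 2, len = 100, n_loci = 40, qtn = 4, snp = 6,
                     seed = 1) {
  build_map(n_chr, rep(len, n_chr), n_loci, qtn, snp, seed = seed)
}

# population with prescribed haplotypes on a 1-chromosome map
pop_from_haps <- function(hap, len = 100, pos = NULL) {
  L <- ncol(hap)
  map <- build_map(1, len, L, 0, 0, seed = 1)
  if (!is.null(pos)) map$pos <- pos
  storage.mode(hap) <- "integer"
  haplo_pop(hap, map)
}

# random centered marker matrix and the two GBLUP kernels
sim_kernels <- function(n, m, seed) {
  set.seed(seed)
  G <- matrix(sample(c(-1L, 0L, 1L), n * m, replace = TRUE), n, m)
  M <- sweep(G, 2, colMeans(G))
  attr(M, "marker_means") <- colMeans(G)
  Ga <- additive_grm(M)
  list(M = M, Ga = Ga, Gaa_norm = epistatic_grm(Ga)$Gaa_norm)
}

# y drawn from the two-kernel mixed model with known components
sim_gblup_y <- function(Ga, Gaa_norm, mu, s_a, s_aa, s_e, seed) {
  set.seed(seed)
  n <- nrow(Ga)
  ridge <- diag(1e-8, n)
  a <- drop(t(chol(s_a * Ga + ridge)) %*% rnorm(n))
  aa <- drop(t(chol(s_aa * Gaa_norm + ridge)) %*% rnorm(n))
  mu + a + aa + rnorm(n, 0, sqrt(s_e))
}

# independent restricted log-likelihood (determinant/solve path, no shared
# code with the fitter's Cholesky recursions)
reml_ll_oracle <- function(y, kernels, sigma, X = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  V <- diag(sigma[length(sigma)], n)
  for (j in seq_along(kernels)) V <- V + sigma[j] * kernels[[j]]
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
                     drop(t(y) %*% P %*% y)))
}

# Henderson mixed-model-equation solve on a whitened scale (u = L w with
# K = LL' from the eigendecomposition), avoiding kernel inversion
mme_oracle <- function(y, Ka, Kaa, sigma, X = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  whiten <- function(K) {
    e <- eigen(K, symmetric = TRUE)
    keep <- e$values > 1e-10 * max(e$values)
    e$vectors[, keep, drop = FALSE] %*% diag(sqrt(e$values[keep]),
                                             sum(keep))
  }
  La <- whiten(Ka)
  Laa <- whiten(Kaa)
  Z <- cbind(La, Laa)
  ra <- ncol(La)
  lam <- c(rep(sigma[4] / sigma[1], ra),
           rep(sigma[4] / sigma[2], ncol(Laa)))
  # sigma = (s_a, s_aa, unused, s_e)
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + diag(lam)))
  rhs <- c(crossprod(X, y), crossprod(Z, y))
  sol <- solve(C, rhs)
  beta <- sol[seq_len(ncol(X))]
  w <- sol[-seq_len(ncol(X))]
  list(beta = beta,
       blup_a = drop(La %*% w[seq_len(ra)]),
       blup_aa = drop(Laa %*% w[-seq_len(ra)]))
}

# grid search over variance components around a center, refined once
grid_reml <- function(y, kernels, center, span = 4, steps = 9) {
  best <- list(ll = -Inf, sigma = center)
  for (pass in 1:2) {
    grids <- lapply(best$sigma, function(s) {
      exp(seq(log(s) - log(span) / pass, log(s) + log(span) / pass,
              length.out = steps))
    })
    for (s1 in grids[[1]]) for (s2 in grids[[2]]) for (s3 in grids[[3]]) {
      ll <- reml_ll_oracle(y, kernels, c(s1, s2, s3))
      if (ll > best$ll) best <- list(ll = ll, sigma = c(s1, s2, s3))
    }
  }
  best
}
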