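#' Trait architecture constructor
#'
#' Low-level constructor for a quantitative trait controlled by additive QTN
#' effects plus optional additive-by-additive epistatic pair effects. The true
#' genetic value of individual i is the bilinear form
#' \deqn{G_i = \sum_k a_k x_{ik} + \sum_{(k,l)} a_{kl} x_{ik} x_{il} - c_0,}
#' where \eqn{x_{ik}} is the -1/0/1 genotype dosage at QTN k centered at the
#' reference (founder) mean, and \eqn{c_0} is a fixed constant absorbing the
#' mean of the epistatic terms in the reference population. Phenotypes are
#' \eqn{Y_i = \mu + G_i + \epsilon_i}, \eqn{\epsilon_i \sim N(0, \sigma_e^2)}.
#'
#' Most users should call [sample_architecture()], which samples and
#' calibrates effects on a founder population.
#'
#' @param qtn_loci Integer locus columns of the QTNs in the map.
#' @param additive_effects Numeric vector `a_k`, one per QTN.
#' @param epistatic_pairs Two-column integer matrix of QTN indices (positions
#'   within `qtn_loci`, not map columns); may have zero rows.
#' @param epistatic_effects Numeric vector `a_kl`, one per pair.
#' @param dosage_centering Per-QTN centering constants (reference-population
#'   mean dosages).
#' @param intercept Trait intercept `mu`.
#' @param error_variance Residual variance `sigma_e^2` (> 0).
#' @param g_offset Constant `c_0` subtracted from the epistatic component.
#' @return An object of class `trait_architecture`.
#' @export
trait_architecture <- function(qtn_loci, additive_effects,
                               epistatic_pairs = matrix(0L, 0, 2),
                               epistatic_effects = numeric(0),
                               dosage_centering = rep(0, length(qtn_loci)),
                               intercept = 0, error_variance = 1,
                               g_offset = 0) {
  epistatic_pairs <- matrix(as.integer(epistatic_pairs), ncol = 2)
  stopifnot(length(additive_effects) == length(qtn_loci),
            length(epistatic_effects) == nrow(epistatic_pairs),
            length(dosage_centering) == length(qtn_loci),
            error_variance > 0)
  if (nrow(epistatic_pairs) > 0) {
    if (any(epistatic_pairs[, 1] == epistatic_pairs[, 2]))
      stop("epistatic pairs must reference two distinct QTNs")
    key <- paste(pmin(epistatic_pairs[, 1], epistatic_pairs[, 2]),
                 pmax(epistatic_pairs[, 1], epistatic_pairs[, 2]))
    if (anyDuplicated(key)) stop("duplicated epistatic pair")
    if (any(epistatic_pairs < 1) || any(epistatic_pairs > length(qtn_loci)))
      stop("epistatic pair index out of range")
  }
  structure(list(qtn_loci = as.integer(qtn_loci),
                 additive_effects = as.numeric(additive_effects),
                 epistatic_pairs = epistatic_pairs,
                 epistatic_effects = as.numeric(epistatic_effects),
                 dosage_centering = as.numeric(dosage_centering),
                 intercept = intercept,
                 error_variance = error_variance,
                 g_offset = g_offset),
            class = "trait_architecture")
}

#' @export
print.trait_architecture <- function(x, ...) {
  cat("Trait architecture:", length(x$qtn_loci), "QTNs,",
      nrow(x$epistatic_pairs), "epistatic pairs\n")
  cat("  intercept:", format(x$intercept), " sigma_e^2:",
      format(x$error_variance), "\n")
  invisible(x)
}

#' Sample and calibrate a trait architecture on a founder population
#'
#' Samples additive QTN effects from the configured distribution, pairs the
#' QTNs into disjoint random pairs carrying additive-by-additive effects, and
#' calibrates the result on the founder population so that
#' (i) the epistatic-to-additive variance ratio Vaa/Va equals
#' `epistasis_ratio` (exactly, by rescaling the pair effects),
#' (ii) the founder genetic values have mean 0 and variance 1 (so that all
#' downstream responses are in founder-genetic-SD units), and
#' (iii) the residual variance gives broad-sense heritability
#' `target_H2 = VG / (VG + sigma_e^2)` in the founders, i.e.
#' `sigma_e^2 = (1 - H2) / H2` once VG = 1.
#'
#' @param map A `genetic_map` with QTN roles assigned.
#' @param founders A `haplo_pop`, polymorphic at every QTN.
#' @param epistasis_ratio Target founder Vaa/Va; 0 means no epistasis.
#' @param target_H2 Founder broad-sense heritability (0 < H2 < 1).
#' @param effect_distribution `"gaussian"` for N(0,1) effects or `"gamma"`
#'   for gamma(shape 1, scale 1) magnitudes with random sign.
#' @param intercept Trait intercept `mu`.
#' @param seed Optional integer seed.
#' @return A calibrated `trait_architecture`.
#' @examples
#' map <- build_map(2, c(100, 100), 60, 6, 6, seed = 1)
#' fnd <- simulate_founders(map, 100, seed = 2)
#' arch <- sample_architecture(map, fnd, epistasis_ratio = 0.5, seed = 3)
#' g <- genetic_value(fnd, arch)
#' c(mean(g$G), var(g$G), var(g$epistatic) / var(g$additive))
#' @export
sample_architecture <- function(map, founders, epistasis_ratio = 0,
                                target_H2 = 0.63,
                                effect_distribution = c("gaussian", "gamma"),
                                intercept = 10, seed = NULL) {
  effect_distribution <- match.arg(effect_distribution)
  stopifnot(inherits(map, "genetic_map"), inherits(founders, "haplo_pop"),
            epistasis_ratio >= 0, target_H2 > 0, target_H2 < 1)
  if (!is.null(seed)) set.seed(seed)

  qtn <- which(map$role == "QTN")
  if (length(qtn) == 0) stop("map has no QTN loci")
  if (epistasis_ratio > 0 && length(qtn) < 2)
    stop("epistasis requires at least 2 QTNs")

  D <- dosage_matrix(founders, qtn)
  if (any(apply(D, 2, function(x) all(x == x[1]))))
    stop("founders must be polymorphic at every QTN")
  centering <- colMeans(D)
  X <- sweep(D, 2, centering)

  draw <- function(n) {
    if (effect_distribution == "gaussian") rnorm(n)
    else rgamma(n, shape = 1, scale = 1) * sample(c(-1, 1), n, replace = TRUE)
  }

  a <- draw(length(qtn))
  add <- drop(X %*% a)
  va <- var(add)
  if (va <= 0) stop("zero additive variance in founders")

  if (epistasis_ratio > 0) {
    ord <- sample(length(qtn))
    n_pairs <- length(qtn) %/% 2L
    pairs <- cbind(ord[seq_len(n_pairs)], ord[n_pairs + seq_len(n_pairs)])
    akl <- draw(n_pairs)
    epi_raw <- drop((X[, pairs[, 1], drop = FALSE] *
                     X[, pairs[, 2], drop = FALSE]) %*% akl)
    ve <- var(epi_raw)
    if (ve <= 0) stop("degenerate epistatic component in founders")
    akl <- akl * sqrt(epistasis_ratio * va / ve)
    epi <- epi_raw * sqrt(epistasis_ratio * va / ve)
  } else {
    pairs <- matrix(0L, 0, 2)
    akl <- numeric(0)
    epi <- rep(0, nrow(X))
  }

  # normalize founder Var(G) to 1; ratio Vaa/Va is invariant to this
  g <- add + epi
  s <- sd(g)
  a <- a / s
  akl <- akl / s
  g_offset <- mean(epi / s)  # additive part has mean 0 by centering

  sigma_e2 <- (1 - target_H2) / target_H2

  trait_architecture(qtn_loci = qtn, additive_effects = a,
                     epistatic_pairs = pairs, epistatic_effects = akl,
                     dosage_centering = centering, intercept = intercept,
                     error_variance = sigma_e2, g_offset = g_offset)
}

#' True genetic values of a population
#'
#' Evaluates the architecture's bilinear form exactly: the additive component
#' is the centered-dosage inner product with the additive effects, the
#' epistatic component sums the pairwise dosage products times the pair
#' effects (minus the fixed reference offset), and `G` is their sum.
#'
#' @param pop A `haplo_pop` on the same map the architecture was built on.
#' @param arch A `trait_architecture`.
#' @return A list with numeric vectors `G`, `additive`, `epistatic`.
#' @export
genetic_value <- function(pop, arch) {
  if (max(arch$qtn_loci) > n_loci(pop$map))
    stop("population loci do not align with the architecture's QTN indexing")
  X <- sweep(dosage_matrix(pop, arch$qtn_loci), 2, arch$dosage_centering)
  add <- unname(drop(X %*% arch$additive_effects))
  if (nrow(arch$epistatic_pairs) > 0) {
    epi <- unname(drop((X[, arch$epistatic_pairs[, 1], drop = FALSE] *
                        X[, arch$epistatic_pairs[, 2], drop = FALSE]) %*%
                       arch$epistatic_effects)) - arch$g_offset
  } else {
    epi <- rep(0, nrow(X)) - arch$g_offset
  }
  list(G = add + epi, additive = add, epistatic = epi)
}

#' Phenotypes of a population
#'
#' `Y_i = mu + G_i + e_i` with i.i.d. Gaussian noise of variance
#' `sigma_e^2` from the architecture.
#'
#' @param pop A `haplo_pop`.
#' @param arch A `trait_architecture`.
#' @param seed Optional integer seed.
#' @return A list with `Y`, `G`, `additive`, `epistatic`.
#' @export
phenotype <- function(pop, arch, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- genetic_value(pop, arch)
  g$Y <- arch$intercept + g$G +
    rnorm(length(g$G), 0, sqrt(arch$error_variance))
  g
}

#' Write a trait architecture as plain-text audit tables
#'
#' @param arch A `trait_architecture`.
#' @param map The `genetic_map` it refers to.
#' @param file Path of the QTN table; the pair table goes to
#'   `paste0(file, ".pairs")` when epistatic pairs exist.
#' @return Invisibly, the QTN table data frame.
#' @export
write_architecture <- function(arch, map, file) {
  qt <- data.frame(qtn = seq_along(arch$qtn_loci),
                   locus = arch$qtn_loci,
                   chromosome = map$chr[arch$qtn_loci],
                   position_cM = map$pos[arch$qtn_loci],
                   additive_effect = arch$additive_effects,
                   centering = arch$dosage_centering)
  write.csv(qt, file, row.names = FALSE)
  if (nrow(arch$epistatic_pairs) > 0) {
    pt <- data.frame(qtn_k = arch$epistatic_pairs[, 1],
                     qtn_l = arch$epistatic_pairs[, 2],
                     effect = arch$epistatic_effects)
    write.csv(pt, paste0(file, ".pairs"), row.names = FALSE)
  }
  invisible(qt)
}
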