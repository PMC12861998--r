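#' Simulate a founder population of pure lines
#'
#' Generates `n_founders` fully homozygous diploid lines (doubled haploids of
#' independently sampled haplotypes). Per-locus allele frequencies are drawn
#' from Wright's mutation-drift stationary distribution Beta(theta, theta)
#' with `theta = 4 * founder_Ne * mu_rate`, giving the U-shaped frequency
#' spectrum typical of a neutral equilibrium population; haplotype alleles are
#' then sampled independently given those frequencies (exchangeable-haplotype
#' model, no ancestral linkage disequilibrium -- in the downstream breeding
#' scheme LD is created by the crossing structure itself).
#'
#' Loci that come out monomorphic across the founder set are resampled
#' (frequency and alleles) up to `max_retries` times so that every retained
#' locus segregates.
#'
#' @param map A `genetic_map`.
#' @param n_founders Number of pure lines (>= 2).
#' @param founder_Ne Effective population size of the equilibrium model.
#' @param mu_rate Per-locus mutation rate; only the product `4 * Ne * mu`
#'   (the Beta shape) matters.
#' @param seed Optional integer seed.
#' @param max_retries Resampling attempts per monomorphic locus.
#' @return A `haplo_pop` of homozygous founders with an `allele_freq`
#'   attribute (A1 frequency per locus across founders).
#' @examples
#' map <- build_map(1, 100, 50, 5, 5, seed = 1)
#' fnd <- simulate_founders(map, 20, seed = 1)
#' all(heterozygosity(fnd) == 0)
#' @export
simulate_founders <- function(map, n_founders, founder_Ne = 1e4,
                              mu_rate = 5e-6, seed = NULL, max_retries = 100L) {
  stopifnot(inherits(map, "genetic_map"), n_founders >= 2)
  if (!is.null(seed)) set.seed(seed)
  theta <- 4 * founder_Ne * mu_rate
  L <- n_loci(map)

  p <- rbeta(L, theta, theta)
  hap1 <- matrix(rbinom(n_founders * L, 1L, rep(p, each = n_founders)),
                 nrow = n_founders, ncol = L)

  counts <- colSums(hap1)
  mono <- which(counts == 0L | counts == n_founders)
  tries <- 0L
  while (length(mono) > 0L && tries < max_retries) {
    tries <- tries + 1L
    p[mono] <- rbeta(length(mono), theta, theta)
    hap1[, mono] <- rbinom(n_founders * length(mono), 1L,
                           rep(p[mono], each = n_founders))
    counts <- colSums(hap1)
    mono <- which(counts == 0L | counts == n_founders)
  }
  if (length(mono) > 0L) {
    stop("could not obtain polymorphic founder alleles at locus (loci) ",
         paste(utils::head(mono, 5), collapse = ", "),
         " after ", max_retries, " retries")
  }

  # doubled haploids: both haplotypes of a founder are identical
  hap <- hap1[rep(seq_len(n_founders), each = 2L), , drop = FALSE]
  storage.mode(hap) <- "integer"
  pop <- haplo_pop(hap, map, ids = paste0("fnd_", seq_len(n_founders)),
                   generation = "founder", validate = FALSE)
  attr(pop, "allele_freq") <- counts / n_founders
  pop
}
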