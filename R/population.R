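#' Haplotype population container
#'
#' A population of diploid individuals stored as a `2n x L` integer matrix of
#' binary alleles (A1 = 1, A2 = 0): rows `2i - 1` and `2i` are the two
#' haplotypes of individual `i`, columns follow the locus order of the map.
#'
#' @param hap Integer matrix of 0/1 alleles, `2n` rows, `n_loci(map)` columns.
#' @param map A `genetic_map`.
#' @param ids Character vector of unique individual identifiers.
#' @param family Identifier of the cross of origin (recycled to `n`).
#' @param generation Generation label, e.g. `"founder"`, `"F1"`, ..., `"F6"`.
#' @param validate Check the allele coding (skipped by internal callers whose
#'   output is 0/1 by construction).
#' @return An object of class `haplo_pop`.
#' @export
haplo_pop <- function(hap, map, ids = NULL, family = NA_integer_,
                      generation = "founder", validate = TRUE) {
  stopifnot(inherits(map, "genetic_map"), is.matrix(hap),
            ncol(hap) == n_loci(map), nrow(hap) %% 2 == 0)
  if (validate && !all(hap == 0L | hap == 1L))
    stop("alleles must be exactly 0 or 1")
  n <- nrow(hap) / 2L
  if (is.null(ids)) ids <- paste0(generation, "_", seq_len(n))
  if (anyDuplicated(ids)) stop("individual ids must be unique")
  stopifnot(length(ids) == n)
  structure(list(hap = hap, map = map, ids = as.character(ids),
                 family = rep_len(family, n), generation = generation),
            class = "haplo_pop")
}

#' @export
print.haplo_pop <- function(x, ...) {
  cat("Haplotype population:", n_ind(x), "individuals (", x$generation,
      "),", n_loci(x$map), "loci\n")
  invisible(x)
}

#' Number of individuals in a population
#' @param pop A `haplo_pop`.
#' @return Integer count.
#' @export
n_ind <- function(pop) nrow(pop$hap) / 2L

#' Subset a population by individual index
#' @param pop A `haplo_pop`.
#' @param i Integer vector of individual indices (may reorder or repeat).
#' @return A `haplo_pop` with the selected individuals.
#' @export
subset_pop <- function(pop, i) {
  i <- as.integer(i)
  stopifnot(all(i >= 1L), all(i <= n_ind(pop)))
  rows <- as.vector(rbind(2L * i - 1L, 2L * i))
  ids <- pop$ids[i]
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = ".")
  haplo_pop(pop$hap[rows, , drop = FALSE], pop$map, ids = ids,
            family = pop$family[i], generation = pop$generation,
            validate = FALSE)
}

#' Genotype dosage matrix
#'
#' Codes genotypes with the -1/0/1 convention (A2A2 = -1, A1A2 = 0,
#' A1A1 = 1), i.e. the A1 allele count minus 1.
#'
#' @param pop A `haplo_pop`.
#' @param loci Optional integer vector of locus columns (default all).
#' @return Numeric `n x length(loci)` matrix with individual ids as rownames.
#' @export
dosage_matrix <- function(pop, loci = NULL) {
  h <- pop$hap
  n <- nrow(h) / 2L
  odd <- seq.int(1L, 2L * n, by = 2L)
  if (!is.null(loci)) h <- h[, loci, drop = FALSE]
  d <- h[odd, , drop = FALSE] + h[odd + 1L, , drop = FALSE] - 1L
  storage.mode(d) <- "double"
  rownames(d) <- pop$ids
  d
}

#' Proportion of heterozygous genotypes per individual
#' @param pop A `haplo_pop`.
#' @param loci Optional locus subset.
#' @return Numeric vector of per-individual heterozygosity.
#' @export
heterozygosity <- function(pop, loci = NULL) {
  h <- pop$hap
  if (!is.null(loci)) h <- h[, loci, drop = FALSE]
  n <- nrow(h) / 2L
  odd <- seq.int(1L, 2L * n, by = 2L)
  rowMeans(h[odd, , drop = FALSE] != h[odd + 1L, , drop = FALSE])
}

#' Combine populations over the same map
#' @param ... `haplo_pop` objects sharing one map.
#' @param generation Generation label of the result (default from first).
#' @return A `haplo_pop`.
#' @export
bind_pops <- function(..., generation = NULL) {
  pops <- list(...)
  stopifnot(length(pops) >= 1)
  L <- vapply(pops, function(p) n_loci(p$map), 1L)
  if (length(unique(L)) != 1) stop("populations must share one locus set")
  ids <- make.unique(unlist(lapply(pops, `[[`, "ids")), sep = ".")
  haplo_pop(do.call(rbind, lapply(pops, `[[`, "hap")), pops[[1]]$map,
            ids = ids,
            family = unlist(lapply(pops, `[[`, "family")),
            generation = generation %||% pops[[1]]$generation,
            validate = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
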