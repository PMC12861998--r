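#' Crossing plan
#'
#' A table of crosses: mother id, father id, and number of progeny per cross.
#' Selfing is expressed as `mother == father`.
#'
#' @param mother,father Character or integer ids of parents.
#' @param n_progeny Progeny per cross (recycled).
#' @param generation Generation label of the progeny.
#' @return A `cross_plan` data frame.
#' @export
cross_plan <- function(mother, father, n_progeny = 1L, generation = "F1") {
  stopifnot(length(mother) == length(father))
  n_progeny <- rep_len(as.integer(n_progeny), length(mother))
  if (any(n_progeny < 1L)) stop("n_progeny must be >= 1")
  structure(data.frame(mother = as.character(mother),
                       father = as.character(father),
                       n_progeny = n_progeny,
                       stringsAsFactors = FALSE),
            generation = generation, class = c("cross_plan", "data.frame"))
}

#' Draw random biparental pairs from a parent set
#'
#' When `n_crosses <= n_parents / 2` parents are paired without replacement;
#' otherwise pairs are drawn uniformly at random with replacement, excluding
#' self-pairs, so that many crosses can be formed from few parents.
#'
#' @param ids Parent identifiers.
#' @param n_crosses Number of crosses.
#' @param n_progeny Progeny per cross.
#' @param generation Label of the progeny generation.
#' @return A `cross_plan`.
#' @export
random_pairs <- function(ids, n_crosses, n_progeny = 1L, generation = "F1") {
  n <- length(ids)
  stopifnot(n >= 2, n_crosses >= 1)
  if (n_crosses <= n %/% 2L) {
    pick <- sample(ids, 2L * n_crosses)
    mother <- pick[seq_len(n_crosses)]
    father <- pick[n_crosses + seq_len(n_crosses)]
  } else {
    mother <- character(n_crosses)
    father <- character(n_crosses)
    for (i in seq_len(n_crosses)) {
      pr <- sample(ids, 2L)
      mother[i] <- pr[1L]
      father[i] <- pr[2L]
    }
  }
  cross_plan(mother, father, n_progeny, generation)
}

#' Single meiosis
#'
#' Draws one recombinant gamete from an individual under the Haldane model:
#' Poisson(chromosome length in Morgans) crossovers at uniform positions, no
#' interference, random starting haplotype.
#'
#' @param pop A `haplo_pop`.
#' @param i Individual index.
#' @return Integer vector of gamete alleles over the map's loci.
#' @export
meiosis <- function(pop, i = 1L) {
  stopifnot(i >= 1, i <= n_ind(pop))
  off <- chr_offsets(pop$map)
  drop(cpp_gametes(pop$hap, as.integer(2L * i - 1L), pop$map$pos,
                   off$first, off$nloci, pop$map$chr_lengths))
}

#' Perform the crosses of a plan
#'
#' Each progeny receives one maternal and one paternal recombinant gamete.
#' The progeny family label is the row number of its cross in the plan.
#'
#' @param pop A `haplo_pop` holding the parents.
#' @param plan A `cross_plan`; parent ids must exist in `pop`.
#' @param seed Optional integer seed.
#' @return A `haplo_pop` of `sum(n_progeny)` progeny.
#' @export
make_crosses <- function(pop, plan, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m_idx <- match(plan$mother, pop$ids)
  f_idx <- match(plan$father, pop$ids)
  if (anyNA(m_idx) || anyNA(f_idx)) {
    bad <- unique(c(plan$mother[is.na(m_idx)], plan$father[is.na(f_idx)]))
    stop("unknown parent id(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  reps <- plan$n_progeny
  m_all <- rep.int(m_idx, reps)
  f_all <- rep.int(f_idx, reps)
  fam <- rep.int(seq_len(nrow(plan)), reps)
  off <- chr_offsets(pop$map)
  gm <- cpp_gametes(pop$hap, 2L * m_all - 1L, pop$map$pos,
                    off$first, off$nloci, pop$map$chr_lengths)
  gf <- cpp_gametes(pop$hap, 2L * f_all - 1L, pop$map$pos,
                    off$first, off$nloci, pop$map$chr_lengths)
  n <- length(m_all)
  hap <- matrix(0L, nrow = 2L * n, ncol = n_loci(pop$map))
  hap[seq.int(1L, 2L * n, 2L), ] <- gm
  hap[seq.int(2L, 2L * n, 2L), ] <- gf
  gen <- attr(plan, "generation") %||% "F1"
  haplo_pop(hap, pop$map, ids = paste0(gen, "_", fam, "_", sequence(reps)),
            family = fam, generation = gen, validate = FALSE)
}

#' Advance a population by selfing (single-seed descent)
#'
#' Replaces every individual by one selfed descendant per generation, keeping
#' ids aligned with the input so that lineages can be traced (individual `i`
#' of the output is the descendant of individual `i` of the input). The
#' generation label is incremented per selfing (F2 -> F3 -> ...).
#'
#' @param pop A `haplo_pop`.
#' @param n_generations Number of selfing generations (>= 1).
#' @param seed Optional integer seed.
#' @return A `haplo_pop` of the same size.
#' @export
self_advance <- function(pop, n_generations = 1L, seed = NULL) {
  stopifnot(n_generations >= 1)
  if (!is.null(seed)) set.seed(seed)
  off <- chr_offsets(pop$map)
  hap <- pop$hap
  n <- n_ind(pop)
  rows <- 2L * seq_len(n) - 1L
  for (g in seq_len(n_generations)) {
    g1 <- cpp_gametes(hap, rows, pop$map$pos, off$first, off$nloci,
                      pop$map$chr_lengths)
    g2 <- cpp_gametes(hap, rows, pop$map$pos, off$first, off$nloci,
                      pop$map$chr_lengths)
    hap <- matrix(0L, nrow = 2L * n, ncol = ncol(hap))
    hap[seq.int(1L, 2L * n, 2L), ] <- g1
    hap[seq.int(2L, 2L * n, 2L), ] <- g2
  }
  haplo_pop(hap, pop$map, ids = pop$ids, family = pop$family,
            generation = next_generation(pop$generation, n_generations),
            validate = FALSE)
}

next_generation <- function(gen, by = 1L) {
  num <- suppressWarnings(as.integer(sub("^F", "", gen)))
  if (is.na(num)) return(gen)
  paste0("F", num + by)
}
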