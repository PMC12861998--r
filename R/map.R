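#' Build a genetic map with QTN and SNP roles
#'
#' Lays out a fixed number of segregating sites on a set of chromosomes,
#' allocating sites to chromosomes proportionally to their genetic length
#' (largest-remainder rounding) and placing them on an even centiMorgan grid
#' along each chromosome. A subset of sites on every chromosome is labelled
#' `SNP` (uniformly spaced among the chromosome's sites, emulating an evenly
#' distributed genotyping panel) and a disjoint subset is labelled `QTN`
#' (sampled at random from the remaining sites). All other sites are `neutral`.
#'
#' The defaults reproduce a rice-like genome: 12 chromosomes of 100 cM,
#' 1644 sites, 30 QTNs and 45 panel SNPs per chromosome.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chr_lengths_cM Numeric vector of chromosome lengths in centiMorgans.
#' @param n_loci_total Total number of segregating sites across the genome.
#' @param n_qtn_per_chr Number of causal (QTN) sites per chromosome.
#' @param n_snp_per_chr Number of panel SNP sites per chromosome.
#' @param seed Optional integer seed controlling QTN placement.
#' @return An object of class `genetic_map`: a list with `n_chr`,
#'   `chr_lengths`, and per-locus vectors `chr` (chromosome index), `pos`
#'   (chromosome-local position, cM) and `role` (`"QTN"`, `"SNP"` or
#'   `"neutral"`).
#' @examples
#' map <- build_map(seed = 1)
#' table(map$role)
#' @export
build_map <- function(n_chromosomes = 12,
                      chr_lengths_cM = rep(100, n_chromosomes),
                      n_loci_total = 1644,
                      n_qtn_per_chr = 30,
                      n_snp_per_chr = 45,
                      seed = NULL) {
  stopifnot(n_chromosomes >= 1, length(chr_lengths_cM) == n_chromosomes,
            all(chr_lengths_cM > 0), n_loci_total >= n_chromosomes,
            n_qtn_per_chr >= 0, n_snp_per_chr >= 0)
  if (!is.null(seed)) set.seed(seed)

  # largest-remainder allocation proportional to cM length, >= 1 per chromosome
  share <- n_loci_total * chr_lengths_cM / sum(chr_lengths_cM)
  n_chr_loci <- pmax(1L, floor(share))
  rem <- n_loci_total - sum(n_chr_loci)
  if (rem > 0) {
    ord <- order(share - floor(share), decreasing = TRUE)
    add <- rep_len(ord, rem)
    for (i in add) n_chr_loci[i] <- n_chr_loci[i] + 1L
  } else if (rem < 0) {
    ord <- order(share - floor(share))
    k <- 0L
    while (rem < 0) {
      k <- k %% n_chromosomes + 1L
      i <- ord[k]
      if (n_chr_loci[i] > 1L) { n_chr_loci[i] <- n_chr_loci[i] - 1L; rem <- rem + 1L }
    }
  }

  need <- n_qtn_per_chr + n_snp_per_chr
  if (any(n_chr_loci < need)) {
    stop("role demand (", need, " QTN+SNP per chromosome) exceeds locus supply on chromosome(s) ",
         paste(which(n_chr_loci < need), collapse = ", "))
  }

  chr <- rep.int(seq_len(n_chromosomes), n_chr_loci)
  pos <- unlist(lapply(seq_len(n_chromosomes), function(i) {
    m <- n_chr_loci[i]
    if (m == 1L) chr_lengths_cM[i] / 2 else seq(0, chr_lengths_cM[i], length.out = m)
  }), use.names = FALSE)

  role <- rep("neutral", length(chr))
  for (i in seq_len(n_chromosomes)) {
    idx <- which(chr == i)
    m <- length(idx)
    snp_local <- if (n_snp_per_chr > 0) {
      unique(round(seq(1, m, length.out = n_snp_per_chr)))
    } else integer(0)
    # even rounding can collide on short chromosomes; pad from unused sites
    while (length(snp_local) < n_snp_per_chr) {
      free <- setdiff(seq_len(m), snp_local)
      snp_local <- sort(c(snp_local, free[1L]))
    }
    role[idx[snp_local]] <- "SNP"
    eligible <- setdiff(seq_len(m), snp_local)
    if (n_qtn_per_chr > 0) {
      qtn_local <- sort(sample(eligible, n_qtn_per_chr))
      role[idx[qtn_local]] <- "QTN"
    }
  }

  structure(list(n_chr = n_chromosomes,
                 chr_lengths = as.numeric(chr_lengths_cM),
                 chr = chr, pos = pos, role = role),
            class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("Genetic map:", length(x$chr), "loci on", x$n_chr, "chromosomes (",
      sum(x$chr_lengths), "cM total )\n")
  cat("  roles:", sum(x$role == "QTN"), "QTN,", sum(x$role == "SNP"), "SNP,",
      sum(x$role == "neutral"), "neutral\n")
  invisible(x)
}

#' Number of loci in a genetic map
#' @param map A `genetic_map`.
#' @return Integer locus count.
#' @export
n_loci <- function(map) length(map$chr)

# 1-based index of the first locus of each chromosome and per-chromosome counts
chr_offsets <- function(map) {
  n_per <- tabulate(map$chr, nbins = map$n_chr)
  list(first = cumsum(c(1L, n_per[-map$n_chr])), nloci = n_per)
}
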