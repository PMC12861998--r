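#' Read a plain-text key-value scenario configuration
#'
#' Parses files of `key = value` (or `key: value`) lines; `#` starts a
#' comment, commas separate list values. Recognized keys mirror the
#' [scenario_grid()] arguments (`contexts`, `progeny_sizes`,
#' `epistasis_ratios`, `n_replicates`, `master_seed`, `scale`, `n_cycles`,
#' `target_H2`) plus the preset overrides (`n_founders`, `n_loci`,
#' `n_qtn_per_chr`, `n_snp_per_chr`, `n_chromosomes`, `chr_lengths_cM`,
#' `n_train_max`, `budget_F2_cap`).
#'
#' @param path Configuration file path.
#' @return A `scenario_grid`.
#' @export
read_scenario_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*[=:]\\s*(.*)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad)) stop("cannot parse configuration line(s): ",
                     paste(utils::head(lines[bad], 3), collapse = "; "))
  keys <- vapply(kv, `[`, "", 2L)
  vals <- lapply(kv, function(m) {
    parts <- trimws(strsplit(m[3], ",")[[1]])
    num <- suppressWarnings(as.numeric(parts))
    if (anyNA(num)) parts else num
  })
  names(vals) <- keys
  do.call(scenario_grid, vals)
}

#' Export genotypes as a dosage matrix file
#'
#' Plain-text matrix with the -1/0/1 dosage convention, individuals in rows,
#' loci in columns.
#'
#' @param pop A `haplo_pop`.
#' @param file Output path (CSV).
#' @param loci Optional locus subset.
#' @return Invisibly `NULL`.
#' @export
write_dosage <- function(pop, file, loci = NULL) {
  D <- dosage_matrix(pop, loci)
  idx <- if (is.null(loci)) seq_len(n_loci(pop$map)) else loci
  colnames(D) <- sprintf("chr%d_%.3fcM", pop$map$chr[idx], pop$map$pos[idx])
  write.csv(D, file)
  invisible(NULL)
}

#' Export genotypes as a minimal diploid VCF
#'
#' VCFv4.2 text with one contig per chromosome, phased `GT` genotypes (the
#' two stored haplotypes), and base-pair positions taken as
#' `round(cM * 1e4)` on an arbitrary physical scale.
#'
#' @param pop A `haplo_pop`.
#' @param file Output path.
#' @return Invisibly `NULL`.
#' @export
write_vcf <- function(pop, file) {
  map <- pop$map
  n <- n_ind(pop)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=epigain",
               sprintf("##contig=<ID=chr%d,length=%d>", seq_len(map$n_chr),
                       as.integer(map$chr_lengths * 1e4) + 1L),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", pop$ids), collapse = "\t"), con)
  odd <- seq.int(1L, 2L * n, by = 2L)
  for (j in seq_len(n_loci(map))) {
    # allele 1 (A1) is ALT, allele 0 (A2) is REF
    gt <- paste(pop$hap[odd, j], pop$hap[odd + 1L, j], sep = "|")
    writeLines(paste(c(sprintf("chr%d", map$chr[j]),
                       as.integer(round(map$pos[j] * 1e4)) + 1L,
                       sprintf("locus_%d", j), "A", "T", ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(NULL)
}
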