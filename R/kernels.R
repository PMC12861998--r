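#' Centered marker matrix
#'
#' Codes the panel SNPs with the -1/0/1 dosage convention and centers each
#' marker at its mean over the same individuals: `M = G - 1 xbar'`.
#'
#' @param pop A `haplo_pop`.
#' @param snp_subset Integer locus columns of the markers; defaults to the
#'   map's `SNP`-role loci.
#' @return Numeric `n x m` matrix with attribute `marker_means` (`xbar`).
#' @export
code_and_center <- function(pop, snp_subset = NULL) {
  if (is.null(snp_subset)) snp_subset <- which(pop$map$role == "SNP")
  if (length(snp_subset) == 0) stop("empty SNP set")
  G <- dosage_matrix(pop, snp_subset)
  xbar <- colMeans(G)
  M <- sweep(G, 2, xbar)
  attr(M, "marker_means") <- xbar
  M
}

#' Additive genomic relationship matrix
#'
#' VanRaden-style GRM from a centered marker matrix. The default normalizer
#' is `s = tr(MM') / n`, so that the mean diagonal of `Ga` is exactly 1 (the
#' same unit-trace convention used for the epistatic kernel); the classical
#' VanRaden denominator `2 * sum(p_k * q_k)` is available via
#' `method = "vanraden"` (it differs only by a scalar, which a variance
#' component absorbs).
#'
#' @param M Centered marker matrix from [code_and_center()].
#' @param method `"trace"` (default) or `"vanraden"`.
#' @return Symmetric PSD `n x n` matrix.
#' @export
additive_grm <- function(M, method = c("trace", "vanraden")) {
  method <- match.arg(method)
  ss <- sum(M * M)
  if (ss <= 0) stop("markers carry no variance (all-zero centered matrix)")
  s <- if (method == "trace") {
    ss / nrow(M)
  } else {
    xbar <- attr(M, "marker_means")
    if (is.null(xbar)) stop("vanraden normalizer needs the marker_means attribute")
    p <- (xbar + 1) / 2
    2 * sum(p * (1 - p))
  }
  tcrossprod(M) / s
}

#' Additive-by-additive epistatic relationship matrices
#'
#' The raw epistatic kernel is the Hadamard square of the additive GRM,
#' `Gaa = Ga o Ga`; the normalized kernel rescales it so the mean diagonal is
#' exactly 1: `Gaa' = Gaa / (tr(Gaa) / n)`.
#'
#' @param Ga Additive GRM.
#' @return List with `Gaa` and `Gaa_norm`.
#' @export
epistatic_grm <- function(Ga) {
  stopifnot(is.matrix(Ga), nrow(Ga) == ncol(Ga))
  Gaa <- Ga * Ga
  Gaa_norm <- Gaa / (sum(diag(Gaa)) / nrow(Gaa))
  list(Gaa = Gaa, Gaa_norm = Gaa_norm)
}

#' Build the full kernel set for a population
#'
#' Convenience wrapper returning the centered marker matrix, the additive
#' GRM and the raw and normalized epistatic kernels.
#'
#' @param pop A `haplo_pop`.
#' @param snp_subset Optional marker locus columns (default map SNPs).
#' @param method GRM normalizer, see [additive_grm()].
#' @return An object of class `kernel_set`: list with `M`, `Ga`, `Gaa`,
#'   `Gaa_norm`, `marker_means`.
#' @export
build_kernels <- function(pop, snp_subset = NULL, method = "trace") {
  M <- code_and_center(pop, snp_subset)
  Ga <- additive_grm(M, method)
  ep <- epistatic_grm(Ga)
  structure(list(M = M, Ga = Ga, Gaa = ep$Gaa, Gaa_norm = ep$Gaa_norm,
                 marker_means = attr(M, "marker_means")),
            class = "kernel_set")
}

#' @export
print.kernel_set <- function(x, ...) {
  cat("Kernel set:", nrow(x$M), "individuals x", ncol(x$M), "markers\n")
  cat("  mean diag Ga:", format(mean(diag(x$Ga))),
      " mean diag Gaa':", format(mean(diag(x$Gaa_norm))), "\n")
  invisible(x)
}

#' Export a kernel matrix with individual-id headers
#' @param K Square kernel matrix with dimnames or an id vector.
#' @param ids Individual ids (defaults to rownames).
#' @param file Output path (CSV).
#' @return Invisibly `NULL`.
#' @export
write_kernel <- function(K, file, ids = rownames(K)) {
  if (is.null(ids)) ids <- paste0("ind_", seq_len(nrow(K)))
  dimnames(K) <- list(ids, ids)
  write.csv(K, file)
  invisible(NULL)
}
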