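#' Prediction accuracy
#'
#' Pearson correlation between true and predicted genetic values.
#'
#' @param true_G,predicted Numeric vectors of equal length (>= 3).
#' @return Correlation in `[-1, 1]`, or `NA` (with a warning) when either
#'   vector has zero variance.
#' @export
accuracy <- function(true_G, predicted) {
  stopifnot(length(true_G) == length(predicted), length(true_G) >= 3)
  if (sd(true_G) == 0 || sd(predicted) == 0) {
    warning("zero variance; accuracy undefined")
    return(NA_real_)
  }
  cor(true_G, predicted)
}

#' Response to selection
#'
#' `R_t = mean G of the parents at cycle t - mean G of the population at
#' cycle 0`.
#'
#' @param parents_mean_t Parents' mean genetic value at cycle t.
#' @param pop_mean_0 Population mean genetic value at cycle 0.
#' @return Numeric response (same units as G).
#' @export
response_to_selection <- function(parents_mean_t, pop_mean_0) {
  parents_mean_t - pop_mean_0
}

#' Annualized relative response
#'
#' `R%/yr = (100 / t) * (G_t - G_0) / |G_0|`, the accumulated gain relative
#' to the initial population, per year of the simulation horizon.
#'
#' @param G_t Mean genetic value at the horizon (same series as `G_0`).
#' @param G_0 Mean genetic value at cycle 0.
#' @param t_years Horizon in years (50 for the canonical 10-cycle program).
#' @param tol Baselines with `|G_0| < tol` are flagged unstable and return
#'   `NA` with a warning.
#' @return Percent per year.
#' @export
annualized_response <- function(G_t, G_0, t_years, tol = 1e-8) {
  stopifnot(t_years > 0)
  out <- (100 / t_years) * (G_t - G_0) / abs(G_0)
  unstable <- abs(G_0) < tol
  if (any(unstable)) {
    warning("baseline mean below tolerance; annualized response undefined")
    out[unstable] <- NA_real_
  }
  out
}

#' True variance components of a population
#'
#' Variances, over individuals, of the architecture-defined additive and
#' epistatic components of the true genetic value (not REML estimates).
#'
#' @param pop A `haplo_pop`.
#' @param arch A `trait_architecture`.
#' @return Named vector `c(Va, Vaa)`.
#' @export
true_variance_components <- function(pop, arch) {
  g <- genetic_value(pop, arch)
  if (length(g$G) < 2) return(c(Va = 0, Vaa = 0))
  c(Va = var(g$additive), Vaa = var(g$epistatic))
}

#' Relativize a per-cycle series to its cycle-0 value
#'
#' @param x Numeric series, cycle 0 first.
#' @param baseline Baseline value (default `x[1]`).
#' @param type `"ratio"` (proportion of baseline, cycle 0 -> 1) or
#'   `"difference"` (cycle 0 -> 0).
#' @param tol Ratios with `|baseline| < tol` return `NA` with a warning.
#' @return Numeric series of relativized values.
#' @export
relativize <- function(x, baseline = x[1], type = c("ratio", "difference"),
                       tol = 1e-12) {
  type <- match.arg(type)
  stopifnot(is.finite(baseline))
  if (type == "difference") return(x - baseline)
  if (abs(baseline) < tol) {
    warning("zero baseline; relativized series undefined")
    return(rep(NA_real_, length(x)))
  }
  x / baseline
}

#' Omega-squared effect size of a one-way layout
#'
#' Classical omega-squared, `(SSb - (k - 1) MSw) / (SSt + MSw)`; negative
#' estimates are truncated at 0 for reporting.
#'
#' @param values Numeric response vector.
#' @param groups Grouping factor/vector.
#' @return Omega-squared in `[0, 1]`.
#' @export
omega_squared <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  n <- length(values)
  gm <- mean(values)
  mg <- tapply(values, groups, mean)
  ng <- tabulate(groups)
  ssb <- sum(ng * (mg - gm)^2)
  ssw <- sum((values - mg[groups])^2)
  msw <- ssw / (n - k)
  max(0, (ssb - (k - 1) * msw) / (ssb + ssw + msw))
}

#' Games-Howell pairwise comparisons
#'
#' Pairwise tests for unequal variances and sample sizes: for each pair the
#' Welch t statistic is referred to the studentized-range distribution with
#' Welch-Satterthwaite degrees of freedom (`q = |t| * sqrt(2)`), optionally
#' followed by Bonferroni adjustment across pairs as an extra guard.
#'
#' @param values Numeric response vector.
#' @param groups Grouping factor/vector (>= 2 groups, >= 3 values each).
#' @param p_adjust Adjustment method over pairs (default `"bonferroni"`,
#'   `"none"` to report the raw Games-Howell p values).
#' @return Data frame with one row per unordered pair: group labels, mean
#'   difference, standard error, t, df, `p` (Games-Howell) and `p_adj`.
#' @export
games_howell <- function(values, groups, p_adjust = "bonferroni") {
  groups <- factor(groups)
  k <- nlevels(groups)
  stopifnot(k >= 2)
  ng <- tabulate(groups)
  if (any(ng < 3)) stop("each group needs at least 3 observations")
  mg <- tapply(values, groups, mean)
  vg <- tapply(values, groups, var)
  pairs <- utils::combn(k, 2)
  res <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se2 <- vg[[i]] / ng[[i]] + vg[[j]] / ng[[j]]
    tstat <- (mg[[i]] - mg[[j]]) / sqrt(se2)
    df <- se2^2 / ((vg[[i]] / ng[[i]])^2 / (ng[[i]] - 1) +
                   (vg[[j]] / ng[[j]])^2 / (ng[[j]] - 1))
    p <- 1 - ptukey(abs(tstat) * sqrt(2), nmeans = k, df = df)
    c(diff = mg[[i]] - mg[[j]], se = sqrt(se2), t = tstat, df = df, p = p)
  })
  out <- data.frame(group1 = levels(groups)[pairs[1, ]],
                    group2 = levels(groups)[pairs[2, ]],
                    t(res))
  out$p_adj <- stats::p.adjust(out$p, method = p_adjust)
  out
}

#' Compare progeny sizes across replicates
#'
#' The across-replicate comparison of a response metric between progeny-size
#' groups: Welch's heteroscedastic one-way ANOVA, the omega-squared effect
#' size, and Games-Howell pairwise tests (Bonferroni-adjusted).
#'
#' @param values Per-replicate responses (e.g. cumulative response at the
#'   horizon).
#' @param sizes Progeny-size label of each value (>= 2 groups, >= 3
#'   replicates each).
#' @return An object of class `size_comparison`: list with `welch`
#'   (statistic, df, p.value), `omega_sq`, `pairwise` (Games-Howell table)
#'   and per-group summaries.
#' @export
compare_progeny_sizes <- function(values, sizes) {
  sizes <- factor(sizes)
  stopifnot(nlevels(sizes) >= 2, all(tabulate(sizes) >= 3))
  wt <- oneway.test(values ~ sizes, var.equal = FALSE)
  groupsum <- data.frame(size = levels(sizes),
                         n = tabulate(sizes),
                         mean = as.numeric(tapply(values, sizes, mean)),
                         sd = as.numeric(tapply(values, sizes, sd)))
  structure(list(welch = list(statistic = unname(wt$statistic),
                              df = unname(wt$parameter),
                              p.value = wt$p.value),
                 omega_sq = omega_squared(values, sizes),
                 pairwise = games_howell(values, sizes),
                 groups = groupsum),
            class = "size_comparison")
}

#' @export
print.size_comparison <- function(x, ...) {
  cat("Welch ANOVA: F =", format(x$welch$statistic, digits = 4),
      " df = (", paste(format(x$welch$df, digits = 4), collapse = ", "),
      ")  p =", format.pval(x$welch$p.value), "\n")
  cat("omega-squared:", round(x$omega_sq, 3), "\n")
  cat("group means:\n")
  print(x$groups, row.names = FALSE)
  cat("Games-Howell (Bonferroni-adjusted):\n")
  print(x$pairwise[, c("group1", "group2", "diff", "p", "p_adj")],
        row.names = FALSE, digits = 4)
  invisible(x)
}
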