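#' Burn-in configuration
#'
#' Three 5-year cycles of classical phenotypic pedigree selection establish
#' the base population before genomic selection starts: random crosses are
#' advanced to F2 (100 individuals per progeny by default), truncation
#' selection on phenotype retains the top fraction at F2, F3 and F4, new
#' parents are selected at F5 and the best line at F6.
#'
#' @param n_crosses Crosses per burn-in cycle.
#' @param progeny_per_cross F2 individuals per cross.
#' @param n_cycles Burn-in cycles.
#' @param keep_fractions Fractions of the census retained at F2, F3 and F4
#'   (length 3).
#' @param select_on How each of the three retention stages picks survivors:
#'   `"phenotype"` (truncation on single-plant phenotype) or `"random"`
#'   (trait-blind culling, emulating the logistic line attrition of a
#'   pedigree program before replicated line evaluation). The default culls
#'   at random at F2 and F3 and applies phenotypic truncation from F4 on,
#'   where line rows make phenotypic selection realistic; together with the
#'   F5 parent choice this keeps the cumulative burn-in gain in the range a
#'   15-year conventional program realizes.
#' @param n_parents Parents selected on phenotype at F5 each cycle.
#' @param years_per_cycle Calendar years per cycle.
#' @return A `burnin_config` list.
#' @export
burnin_config <- function(n_crosses = 160L, progeny_per_cross = 100L,
                          n_cycles = 3L, keep_fractions = c(0.2, 0.2, 0.2),
                          select_on = c("random", "random", "phenotype"),
                          n_parents = 40L, years_per_cycle = 5L) {
  stopifnot(n_crosses >= 1, progeny_per_cross >= 1, n_cycles >= 0,
            length(keep_fractions) == 3, all(keep_fractions > 0),
            all(keep_fractions <= 1), n_parents >= 2,
            length(select_on) == 3,
            all(select_on %in% c("phenotype", "random")))
  structure(list(n_crosses = as.integer(n_crosses),
                 progeny_per_cross = as.integer(progeny_per_cross),
                 n_cycles = as.integer(n_cycles),
                 keep_fractions = keep_fractions,
                 select_on = select_on,
                 n_parents = as.integer(n_parents),
                 years_per_cycle = as.integer(years_per_cycle)),
            class = "burnin_config")
}

#' Genomic-selection scheme configuration
#'
#' Configures one test-and-shelf recurrent genomic-selection scenario. In the
#' `theoretical` context the number of crosses is fixed (default 40) and the
#' F2 census grows with progeny size; in the `budget` context the F2 census
#' is capped (default 4000 individuals) and the number of crosses is
#' `budget_F2_cap / progeny_per_cross`.
#'
#' @param context `"theoretical"` or `"budget"`.
#' @param progeny_per_cross F2 individuals per cross (25, 50, 100 or 200 in
#'   the canonical grid; any positive value is accepted).
#' @param n_parents Parents per cycle (held at 40).
#' @param n_crosses Crosses per cycle; defaults to 40 (theoretical) or
#'   `budget_F2_cap / progeny_per_cross` (budget).
#' @param test_fraction Fraction of the F2 assigned to the phenotyped /
#'   genotyped test group.
#' @param n_test_selected Test individuals selected on F5 phenotype.
#' @param shelf_parent_fraction Fraction of `n_parents` recruited from the
#'   shelf on predicted values.
#' @param n_cycles Genomic-selection cycles.
#' @param years_per_cycle Calendar years per cycle.
#' @param budget_F2_cap F2 census cap in the budget context.
#' @param n_train_frac Fraction of the test group used to train the GBLUP
#'   (random subset; 1 = the whole test group). A fraction keeps the
#'   training-set size proportional to the test group, preserving the
#'   training-size contrast between progeny sizes at reduced cost.
#' @param n_train_max Absolute cap on the training-set size.
#' @param min_test_for_reml Minimum test-group size required to fit REML.
#' @return A `scheme_config` list (with derived `n_shelf_selected`).
#' @export
scheme_config <- function(context = c("theoretical", "budget"),
                          progeny_per_cross = 100L, n_parents = 40L,
                          n_crosses = NULL, test_fraction = 0.2,
                          n_test_selected = 8L, shelf_parent_fraction = 0.8,
                          n_cycles = 10L, years_per_cycle = 5L,
                          budget_F2_cap = 4000L, n_train_frac = 1,
                          n_train_max = Inf, min_test_for_reml = 30L) {
  context <- match.arg(context)
  progeny_per_cross <- as.integer(progeny_per_cross)
  stopifnot(progeny_per_cross >= 1, n_parents >= 2, test_fraction > 0,
            test_fraction < 1, n_cycles >= 0)
  if (is.null(n_crosses)) {
    n_crosses <- if (context == "theoretical") 40L else {
      if (budget_F2_cap %% progeny_per_cross != 0)
        stop("progeny size ", progeny_per_cross,
             " does not divide the F2 budget cap ", budget_F2_cap)
      as.integer(budget_F2_cap / progeny_per_cross)
    }
  }
  n_crosses <- as.integer(n_crosses)
  if (context == "budget" && n_crosses * progeny_per_cross != budget_F2_cap)
    stop("budget context requires n_crosses * progeny_per_cross == ",
         budget_F2_cap)
  n_shelf_selected <- as.integer(round(shelf_parent_fraction * n_parents))
  if (n_test_selected + n_shelf_selected != n_parents)
    stop("n_test_selected + round(shelf_parent_fraction * n_parents) must equal n_parents")
  structure(list(context = context, progeny_per_cross = progeny_per_cross,
                 n_parents = as.integer(n_parents), n_crosses = n_crosses,
                 test_fraction = test_fraction,
                 n_test_selected = as.integer(n_test_selected),
                 shelf_parent_fraction = shelf_parent_fraction,
                 n_shelf_selected = n_shelf_selected,
                 n_cycles = as.integer(n_cycles),
                 years_per_cycle = as.integer(years_per_cycle),
                 budget_F2_cap = as.integer(budget_F2_cap),
                 n_train_frac = n_train_frac,
                 n_train_max = n_train_max,
                 min_test_for_reml = as.integer(min_test_for_reml)),
            class = "scheme_config")
}

#' @export
print.scheme_config <- function(x, ...) {
  cat("GS scheme (", x$context, "): ", x$n_crosses, " crosses x ",
      x$progeny_per_cross, " progeny = ", x$n_crosses * x$progeny_per_cross,
      " F2; ", x$n_cycles, " cycles of ", x$years_per_cycle, " years\n",
      sep = "")
  cat("  parents/cycle:", x$n_parents, "=", x$n_test_selected, "test +",
      x$n_shelf_selected, "shelf\n")
  invisible(x)
}

new_cycle_record <- function(cycle, year, g_pop, best_line_G, parents_mean_G,
                             accuracy = NA_real_, sigma = NULL, n_F2 = NA_integer_,
                             converged = NA) {
  data.frame(cycle = cycle, year = year,
             mean_G = mean(g_pop$G),
             best_line_G = unname(best_line_G),
             Va = if (length(g_pop$G) > 1) var(g_pop$additive) else 0,
             Vaa = if (length(g_pop$G) > 1) var(g_pop$epistatic) else 0,
             accuracy = accuracy,
             parents_mean_G = parents_mean_G,
             sigma_a2_hat = if (is.null(sigma)) NA_real_ else unname(sigma["sigma_a2"]),
             sigma_aa2_hat = if (is.null(sigma)) NA_real_ else unname(sigma["sigma_aa2"]),
             sigma_e2_hat = if (is.null(sigma)) NA_real_ else unname(sigma["sigma_e2"]),
             n_F2 = n_F2, reml_converged = converged,
             row.names = NULL)
}

select_top <- function(values, k) order(values, decreasing = TRUE)[seq_len(k)]

#' Run the burn-in phase
#'
#' Executes the configured cycles of phenotypic pedigree selection starting
#' from the founders and returns the base parents for genomic selection plus
#' the cycle-0 reference record (base-population mean, Va, Vaa).
#'
#' @param founders Founder `haplo_pop`.
#' @param arch Calibrated `trait_architecture`.
#' @param burnin A `burnin_config`.
#' @param seed Optional integer seed.
#' @return List with `parents` (a `haplo_pop` of F6 lines), `baseline`
#'   (one-row cycle-0 record) and `years` (burn-in horizon).
#' @export
run_burnin <- function(founders, arch, burnin = burnin_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  parents <- founders
  best_line_G <- NA_real_
  for (cyc in seq_len(burnin$n_cycles)) {
    plan <- random_pairs(parents$ids, burnin$n_crosses, 1L, "F1")
    f1 <- make_crosses(parents, plan)
    f2 <- make_crosses(f1, cross_plan(f1$ids, f1$ids,
                                      burnin$progeny_per_cross, "F2"))
    pop <- f2
    for (stage in 1:3) {  # retention at F2, F3, F4 (phenotypic or trait-blind)
      keep <- max(burnin$n_parents,
                  ceiling(burnin$keep_fractions[stage] * n_ind(pop)))
      if (keep > n_ind(pop)) stop("selection demand exceeds candidates at burn-in stage ", stage)
      kept <- if (burnin$select_on[stage] == "phenotype") {
        select_top(phenotype(pop, arch)$Y, keep)
      } else {
        sample(n_ind(pop), keep)
      }
      pop <- self_advance(subset_pop(pop, kept), 1L)
    }
    ph5 <- phenotype(pop, arch)
    if (burnin$n_parents > n_ind(pop)) stop("selection demand exceeds F5 candidates")
    sel <- subset_pop(pop, select_top(ph5$Y, burnin$n_parents))
    parents <- self_advance(sel, 1L)  # F6 lines
    ph6 <- phenotype(parents, arch)
    best_line_G <- genetic_value(parents, arch)$G[which.max(ph6$Y)]
  }
  g <- genetic_value(parents, arch)
  baseline <- new_cycle_record(cycle = 0L,
                               year = 0L,
                               g_pop = g,
                               best_line_G = best_line_G,
                               parents_mean_G = mean(g$G))
  list(parents = parents, baseline = baseline,
       years = burnin$n_cycles * burnin$years_per_cycle)
}

# Partitioned kernel blocks for one GS cycle: one kernel construction over
# the union (train + shelf) of F2 genotypes, centered jointly, trace
# normalizers computed on the union, then cut into the blocks the fit and the
# projection need (the shelf x shelf block is never formed).
gs_kernel_blocks <- function(D_train, D_shelf) {
  nt <- nrow(D_train); ns <- nrow(D_shelf); n <- nt + ns
  xbar <- (colSums(D_train) + colSums(D_shelf)) / n
  Mt <- sweep(D_train, 2, xbar)
  Ms <- sweep(D_shelf, 2, xbar)
  ss <- sum(Mt * Mt) + sum(Ms * Ms)
  if (ss <= 0) stop("markers carry no variance in this cycle")
  s_a <- ss / n
  Ga_tt <- tcrossprod(Mt) / s_a
  Ka_cross <- tcrossprod(Mt, Ms) / s_a
  diag_union <- c(rowSums(Mt * Mt), rowSums(Ms * Ms)) / s_a
  c_aa <- mean(diag_union^2)
  list(Ga_tt = Ga_tt, Ka_cross = Ka_cross,
       Gaa_tt = Ga_tt * Ga_tt / c_aa, Kaa_cross = Ka_cross * Ka_cross / c_aa)
}

#' Run one test-and-shelf genomic-selection cycle
#'
#' One 5-year cycle: (1) random crosses among the current parents, advanced
#' to an F2 of `n_crosses x progeny_per_cross` individuals; (2) random split
#' into a test group (`test_fraction`, default 20%) and a shelf (the rest);
#' (3) the test group is advanced by single-seed descent to F5 and
#' phenotyped, and a two-kernel GBLUP is fitted on its F2 marker genotypes;
#' (4) shelf individuals are predicted at F2 by kinship projection and the
#' top `n_shelf_selected` advanced to F5; (5) the `n_test_selected` best test
#' individuals on F5 phenotype join the selected shelf and all are selfed to
#' F6, forming the next cycle's parents; (6) the best F6 line (on phenotype)
#' and the cycle metrics are recorded. Prediction accuracy is the Pearson
#' correlation between projected predictions and true genetic values on the
#' shelf.
#'
#' @param state List with elements `parents` (a `haplo_pop`) and `cycle`.
#' @param arch A `trait_architecture`.
#' @param config A `scheme_config`.
#' @return List with updated `state` and a one-row `record` data frame.
#' @export
run_gs_cycle <- function(state, arch, config) {
  parents <- state$parents
  if (n_ind(parents) != config$n_parents)
    stop("state must hold exactly n_parents parents")
  cycle <- state$cycle + 1L

  # (1) crosses and F2
  plan <- random_pairs(parents$ids, config$n_crosses, 1L, "F1")
  f1 <- make_crosses(parents, plan)
  f2 <- make_crosses(f1, cross_plan(f1$ids, f1$ids,
                                    config$progeny_per_cross, "F2"))
  nF2 <- n_ind(f2)
  g2 <- genetic_value(f2, arch)

  # (2) test / shelf split
  n_test <- round(config$test_fraction * nF2)
  if (n_test < config$min_test_for_reml)
    stop("test group (", n_test, ") smaller than the REML minimum (",
         config$min_test_for_reml, ")")
  test_idx <- sample(nF2, n_test)
  shelf_idx <- setdiff(seq_len(nF2), test_idx)
  if (config$n_shelf_selected > length(shelf_idx))
    stop("selection demand exceeds shelf candidates")
  if (config$n_test_selected > n_test)
    stop("selection demand exceeds test candidates")
  f2_test <- subset_pop(f2, test_idx)
  f2_shelf <- subset_pop(f2, shelf_idx)

  # (3) test advanced to F5, phenotyped; GBLUP trained on F2 genotypes
  f5_test <- self_advance(f2_test, 3L)
  ph5 <- phenotype(f5_test, arch)
  n_train <- min(max(config$min_test_for_reml,
                     ceiling(config$n_train_frac * n_test)),
                 config$n_train_max, n_test)
  train_idx <- if (n_train < n_test) sort(sample(n_test, n_train)) else
    seq_len(n_test)
  snp <- which(f2$map$role == "SNP")
  D_train <- dosage_matrix(f2_test, snp)[train_idx, , drop = FALSE]
  D_shelf <- dosage_matrix(f2_shelf, snp)
  D_all <- rbind(D_train, D_shelf)
  if (sum(sweep(D_all, 2, colMeans(D_all))^2) == 0) {
    # marker panel fixed: genomic prediction carries no information; fall
    # back to the prior mean (shelf choice is then arbitrary)
    fit <- NULL
    yhat_shelf <- rep(mean(ph5$Y[train_idx]), length(shelf_idx))
    acc <- NA_real_
    shelf_sel <- sample(length(shelf_idx), config$n_shelf_selected)
  } else {
    blocks <- gs_kernel_blocks(D_train, D_shelf)
    fit <- fit_gblup(ph5$Y[train_idx], blocks$Ga_tt, blocks$Gaa_tt,
                     init = state$sigma_init)

    # (4) shelf predicted at F2; top fraction advanced to F5
    yhat_shelf <- project_gblup_direct(fit, blocks$Ka_cross, blocks$Kaa_cross)
    acc <- accuracy(g2$G[shelf_idx], as.numeric(yhat_shelf))
    shelf_sel <- select_top(as.numeric(yhat_shelf), config$n_shelf_selected)
  }
  f5_shelf <- self_advance(subset_pop(f2_shelf, shelf_sel), 3L)

  # (5) best test on F5 phenotype + selected shelf -> F6 parents
  test_sel <- select_top(ph5$Y, config$n_test_selected)
  f5_parents <- bind_pops(subset_pop(f5_test, test_sel), f5_shelf,
                          generation = "F5")
  f6 <- self_advance(f5_parents, 1L)
  g6 <- genetic_value(f6, arch)

  # (6) best line on F6 phenotype; metrics
  ph6 <- phenotype(f6, arch)
  record <- new_cycle_record(cycle = cycle,
                             year = cycle * config$years_per_cycle,
                             g_pop = g2,
                             best_line_G = g6$G[which.max(ph6$Y)],
                             parents_mean_G = mean(g6$G),
                             accuracy = acc,
                             sigma = if (is.null(fit)) NULL else fit$sigma,
                             n_F2 = nF2,
                             converged = if (is.null(fit)) NA else fit$converged)
  list(state = list(parents = f6, cycle = cycle,
                    sigma_init = if (is.null(fit)) NULL else fit$sigma),
       record = record)
}

#' Run a full genomic-selection program
#'
#' Runs `n_cycles` sequential test-and-shelf cycles from a burn-in base
#' population. Deterministic for a given seed.
#'
#' @param base Base parents (`haplo_pop`), e.g. from [run_burnin()].
#' @param arch A `trait_architecture`.
#' @param config A `scheme_config`.
#' @param seed Optional integer seed.
#' @param baseline Optional cycle-0 record from [run_burnin()]; when missing
#'   it is computed from `base`.
#' @return A `gs_records` data frame: the baseline row (cycle 0) followed by
#'   one row per cycle with columns `cycle`, `year`, `mean_G`,
#'   `best_line_G`, `Va`, `Vaa`, `accuracy`, `parents_mean_G`,
#'   `sigma_*_hat`, `n_F2`, `reml_converged`.
#' @export
run_program <- function(base, arch, config, seed = NULL, baseline = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(baseline)) {
    g <- genetic_value(base, arch)
    baseline <- new_cycle_record(0L, 0L, g, best_line_G = max(g$G),
                                 parents_mean_G = mean(g$G))
  }
  state <- list(parents = base, cycle = 0L, sigma_init = NULL)
  records <- list(baseline)
  for (cyc in seq_len(config$n_cycles)) {
    step <- run_gs_cycle(state, arch, config)
    state <- step$state
    records[[cyc + 1L]] <- step$record
  }
  out <- do.call(rbind, records)
  class(out) <- c("gs_records", "data.frame")
  out
}

#' Plot genetic-gain trajectories
#'
#' Plots the population-mean genetic value (and optionally the parents'
#' mean) over the simulated years, one line per group when a grouping column
#' is given.
#'
#' @param x A `gs_records` data frame.
#' @param metric Column to plot (default `"mean_G"`).
#' @param group Optional grouping column name (e.g. `"progeny_size"`).
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly `x`.
#' @export
plot.gs_records <- function(x, metric = "mean_G", group = NULL, ...) {
  if (is.null(group)) {
    graphics::plot(x$year, x[[metric]], type = "b", xlab = "year",
                   ylab = metric, ...)
  } else {
    lv <- sort(unique(x[[group]]))
    yrs <- sort(unique(x$year))
    m <- sapply(lv, function(g) {
      sub <- x[x[[group]] == g, ]
      tapply(sub[[metric]], factor(sub$year, levels = yrs), mean)
    })
    graphics::matplot(yrs, m, type = "b", pch = 1, lty = 1, xlab = "year",
                      ylab = metric, ...)
    graphics::legend("topleft", legend = paste(group, lv), col = seq_along(lv),
                     lty = 1, bty = "n")
  }
  invisible(x)
}
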