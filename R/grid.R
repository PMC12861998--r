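#' Define a scenario grid
#'
#' The full factorial of resource contexts, progeny sizes and epistasis
#' levels, with replicate management and a master seed. Two problem-size
#' presets are provided: `"full"` mirrors the canonical study conditions
#' (1000 founders, 1644 loci with 360 QTN / 540 SNP, 100 replicates, whole
#' test group trains the GBLUP), while `"reduced"` is a desk-scale preset
#' (300 founders, 600 loci with 120 QTN / 180 SNP, 10 replicates, GBLUP
#' trained on a random 25% of the test group) that preserves the scheme logic at a
#' fraction of the cost.
#'
#' @param contexts Subset of `c("theoretical", "budget")`.
#' @param progeny_sizes Subset of `c(25, 50, 100, 200)` (any divisors of the
#'   budget cap are accepted).
#' @param epistasis_ratios Subset of `c(0, 0.5, 1)`.
#' @param n_replicates Independent replicates per scenario.
#' @param master_seed Integer master seed; every source of randomness
#'   derives from it.
#' @param scale `"full"` or `"reduced"`.
#' @param n_cycles Genomic-selection cycles per program.
#' @param target_H2 Founder broad-sense heritability.
#' @param ... Overrides for the preset fields (`n_founders`, `n_loci`,
#'   `n_qtn_per_chr`, `n_snp_per_chr`, `n_chromosomes`, `chr_lengths_cM`,
#'   `n_train_frac`, `budget_F2_cap`, `burnin` -- a [burnin_config()]).
#' @return An object of class `scenario_grid`.
#' @export
scenario_grid <- function(contexts = c("theoretical", "budget"),
                          progeny_sizes = c(25, 50, 100, 200),
                          epistasis_ratios = c(0, 0.5, 1),
                          n_replicates = NULL, master_seed = 1L,
                          scale = c("full", "reduced"), n_cycles = 10L,
                          target_H2 = 0.63, ...) {
  scale <- match.arg(scale)
  contexts <- match.arg(contexts, c("theoretical", "budget"),
                        several.ok = TRUE)
  preset <- if (scale == "full") {
    list(n_founders = 1000L, n_chromosomes = 12L,
         chr_lengths_cM = rep(100, 12), n_loci = 1644L,
         n_qtn_per_chr = 30L, n_snp_per_chr = 45L,
         n_train_frac = 1, n_replicates = 100L, budget_F2_cap = 4000L,
         burnin = burnin_config())
  } else {
    list(n_founders = 300L, n_chromosomes = 12L,
         chr_lengths_cM = rep(100, 12), n_loci = 600L,
         n_qtn_per_chr = 10L, n_snp_per_chr = 15L,
         n_train_frac = 0.25, n_replicates = 10L, budget_F2_cap = 4000L,
         burnin = burnin_config())
  }
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(preset))
  if (length(bad)) stop("unknown override(s): ", paste(bad, collapse = ", "))
  preset[names(overrides)] <- overrides
  if (!is.null(n_replicates)) preset$n_replicates <- as.integer(n_replicates)

  structure(c(list(contexts = contexts,
                   progeny_sizes = as.integer(progeny_sizes),
                   epistasis_ratios = as.numeric(epistasis_ratios),
                   master_seed = as.integer(master_seed),
                   scale = scale, n_cycles = as.integer(n_cycles),
                   target_H2 = target_H2),
              preset),
            class = "scenario_grid")
}

#' @export
print.scenario_grid <- function(x, ...) {
  cat("Scenario grid (", x$scale, " scale): ",
      length(x$contexts), " context(s) x ", length(x$progeny_sizes),
      " size(s) x ", length(x$epistasis_ratios), " epistasis level(s), ",
      x$n_replicates, " replicates\n", sep = "")
  invisible(x)
}

#' Expand a grid into fully resolved scenario configurations
#'
#' Full factorial expansion; budget scenarios receive
#' `n_crosses = budget_F2_cap / progeny_size` (an error when the size does
#' not divide the cap), theoretical scenarios 40 crosses.
#'
#' @param grid A `scenario_grid`.
#' @return Data frame with columns `scenario_id`, `context`,
#'   `progeny_size`, `epistasis_ratio`, `n_crosses`.
#' @export
expand_scenarios <- function(grid) {
  stopifnot(inherits(grid, "scenario_grid"))
  df <- expand.grid(context = grid$contexts,
                    progeny_size = grid$progeny_sizes,
                    epistasis_ratio = grid$epistasis_ratios,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) return(cbind(df, n_crosses = integer(0), scenario_id = character(0)))
  df$n_crosses <- ifelse(df$context == "theoretical", 40L,
                         grid$budget_F2_cap %/% df$progeny_size)
  bad <- df$context == "budget" & grid$budget_F2_cap %% df$progeny_size != 0
  if (any(bad))
    stop("progeny size(s) ", paste(unique(df$progeny_size[bad]), collapse = ", "),
         " do not divide the budget cap ", grid$budget_F2_cap)
  df$scenario_id <- sprintf("%s_s%d_e%g", df$context, df$progeny_size,
                            df$epistasis_ratio)
  df[, c("scenario_id", "context", "progeny_size", "epistasis_ratio",
         "n_crosses")]
}

# non-overlapping seed streams derived from the master seed: one block of
# sub-seeds per (replicate, purpose) drawn once from a seeded stream
derive_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run a scenario grid
#'
#' Executes every scenario x replicate run and collects per-cycle records.
#' Within a replicate, the same founder population is used for all epistasis
#' levels and the same burn-in base population (per epistasis level) is
#' reused across all progeny sizes and contexts, coupling the comparisons
#' exactly as a paired design would. Results are independent of execution
#' order; per-replicate seeds are derived from the master seed. When `out`
#' is given the records are appended to a CSV (plus a plain-text manifest),
#' and an interrupted run can be resumed: completed (scenario, replicate)
#' pairs found in the existing file are skipped.
#'
#' @param grid A `scenario_grid`.
#' @param out Optional CSV output path.
#' @param resume Skip (scenario, replicate) pairs already present in `out`.
#' @param verbose Print progress lines.
#' @return A `gs_records` data frame with scenario columns (`replicate`,
#'   `scenario_id`, `context`, `progeny_size`, `epistasis_ratio`, `seed`)
#'   added to the per-cycle metrics.
#' @export
run_scenario_grid <- function(grid, out = NULL, resume = TRUE,
                              verbose = FALSE) {
  scen <- expand_scenarios(grid)
  if (nrow(scen) == 0) return(invisible(data.frame()))
  eps <- sort(unique(scen$epistasis_ratio))
  R <- grid$n_replicates

  done <- NULL
  rows <- list()
  if (!is.null(out) && file.exists(out) && resume) {
    prev <- read.csv(out, stringsAsFactors = FALSE)
    done <- unique(paste(prev$scenario_id, prev$replicate))
    rows <- list(prev)
  }

  # seed layout: per replicate one founder seed, one (burn-in, architecture)
  # seed per epistasis level, one run seed per scenario
  n_per_rep <- 1L + 2L * length(eps) + nrow(scen)
  seeds <- matrix(derive_seeds(grid$master_seed, R * n_per_rep), nrow = R)

  for (r in seq_len(R)) {
    scen_todo <- if (is.null(done)) scen else
      scen[!(paste(scen$scenario_id, r) %in% done), , drop = FALSE]
    if (nrow(scen_todo) == 0) next
    map <- build_map(grid$n_chromosomes, grid$chr_lengths_cM, grid$n_loci,
                     grid$n_qtn_per_chr, grid$n_snp_per_chr,
                     seed = seeds[r, 1L])
    founders <- simulate_founders(map, grid$n_founders, seed = seeds[r, 1L])
    for (ei in seq_along(eps)) {
      if (!any(scen_todo$epistasis_ratio == eps[ei])) next
      arch <- sample_architecture(map, founders, epistasis_ratio = eps[ei],
                                  target_H2 = grid$target_H2,
                                  seed = seeds[r, 1L + 2L * ei - 1L])
      base <- run_burnin(founders, arch, grid$burnin,
                         seed = seeds[r, 1L + 2L * ei])
      for (si in which(scen$epistasis_ratio == eps[ei])) {
        if (!scen$scenario_id[si] %in% scen_todo$scenario_id) next
        cfg <- scheme_config(context = scen$context[si],
                             progeny_per_cross = scen$progeny_size[si],
                             n_crosses = if (scen$context[si] == "theoretical")
                               scen$n_crosses[si] else NULL,
                             n_cycles = grid$n_cycles,
                             budget_F2_cap = grid$budget_F2_cap,
                             n_train_frac = grid$n_train_frac)
        run_seed <- seeds[r, 1L + 2L * length(eps) + si]
        rec <- run_program(base$parents, arch, cfg, seed = run_seed,
                           baseline = base$baseline)
        rec$replicate <- r
        rec$scenario_id <- scen$scenario_id[si]
        rec$context <- scen$context[si]
        rec$progeny_size <- scen$progeny_size[si]
        rec$epistasis_ratio <- scen$epistasis_ratio[si]
        rec$seed <- run_seed
        rows[[length(rows) + 1L]] <- rec
        if (verbose)
          message("replicate ", r, " ", scen$scenario_id[si], " done")
        if (!is.null(out)) {
          write.csv(do.call(rbind, rows), out, row.names = FALSE)
        }
      }
    }
  }
  records <- do.call(rbind, rows)
  class(records) <- c("gs_records", "data.frame")
  if (!is.null(out)) {
    write.csv(records, out, row.names = FALSE)
    manifest <- c(paste("package:", "epigain",
                        as.character(packageVersion("epigain"))),
                  paste("master_seed:", grid$master_seed),
                  paste("scale:", grid$scale),
                  paste("replicates:", grid$n_replicates),
                  paste("scenarios:", paste(scen$scenario_id, collapse = " ")),
                  paste("finished:", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
    writeLines(manifest, paste0(out, ".manifest.txt"))
  }
  invisible(records)
}

#' Per-replicate program outcomes at the horizon
#'
#' Collapses a grid record table to one row per (scenario, replicate) with
#' the cumulative response `R_t` (parents' mean at the final cycle minus the
#' cycle-0 population mean, in founder-genetic-SD units), the annualized
#' relative response (%/yr, parents'-mean series), and the final-cycle
#' prediction accuracy.
#'
#' @param records A `gs_records` table from [run_scenario_grid()].
#' @return Data frame with columns `scenario_id`, `context`,
#'   `progeny_size`, `epistasis_ratio`, `replicate`, `response`,
#'   `annualized_pct`, `final_accuracy`.
#' @export
program_responses <- function(records) {
  stopifnot(all(c("scenario_id", "replicate", "cycle") %in% names(records)))
  keys <- unique(records[, c("scenario_id", "context", "progeny_size",
                             "epistasis_ratio", "replicate")])
  res <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- records[records$scenario_id == keys$scenario_id[i] &
                   records$replicate == keys$replicate[i], ]
    sub <- sub[order(sub$cycle), ]
    t_final <- sub$year[nrow(sub)]
    g0 <- sub$mean_G[1]
    gt <- sub$parents_mean_G[nrow(sub)]
    data.frame(keys[i, ],
               response = response_to_selection(gt, g0),
               annualized_pct = annualized_response(gt, sub$parents_mean_G[1],
                                                    t_final),
               final_accuracy = sub$accuracy[nrow(sub)],
               row.names = NULL)
  })
  do.call(rbind, res)
}

#' Summarize a grid record table
#'
#' Per-scenario, per-cycle means and standard deviations of the main
#' metrics, plus relativized (cycle-0 = 1) mean trajectories.
#'
#' @param records A `gs_records` table.
#' @param file Optional CSV path for the summary.
#' @return Data frame of per-(scenario, cycle) summaries.
#' @export
summarize_records <- function(records, file = NULL) {
  metrics <- c("mean_G", "best_line_G", "Va", "Vaa", "accuracy",
               "parents_mean_G")
  agg <- aggregate(records[metrics],
                   by = records[c("scenario_id", "context", "progeny_size",
                                  "epistasis_ratio", "cycle", "year")],
                   FUN = function(x) mean(x, na.rm = TRUE))
  sds <- aggregate(records[metrics],
                   by = records[c("scenario_id", "cycle")],
                   FUN = function(x) sd(x, na.rm = TRUE))
  names(sds)[-(1:2)] <- paste0(metrics, "_sd")
  out <- merge(agg, sds, by = c("scenario_id", "cycle"))
  out <- out[order(out$scenario_id, out$cycle), ]
  for (id in unique(out$scenario_id)) {
    sel <- out$scenario_id == id
    out$rel_mean_G[sel] <- relativize(out$mean_G[sel])
    out$rel_Va[sel] <- relativize(out$Va[sel])
  }
  if (!is.null(file)) write.csv(out, file, row.names = FALSE)
  out
}
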