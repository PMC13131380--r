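#' Run the full genotyping-error experiment
#'
#' For each replicate: simulate a fresh population, fit the benchmark
#' ssGBLUP (training + validation genotypes, candidates unphenotyped), fit
#' the reduced run (training generations only), back-solve SNP effects,
#' compute indirect predictions under each validation-genotype error rate
#' (all scenarios share the replicate's population and candidates), and
#' evaluate every IP set against the benchmark GEBV. Optionally a
#' training-genotype-error side run re-estimates the SNP effects from
#' perturbed training genotypes (with correct validation genotypes) to
#' measure the inflation of the mean IP. Statistics are aggregated across
#' replicates as mean and SE.
#'
#' Seed discipline: replicate `r` uses master seed `master_seed + r` for the
#' simulation; error injection draws from an independent offset stream so
#' every scenario within a replicate perturbs the identical population.
#'
#' @param config a [sim_config()]; defaults to the [desk_profile()].
#' @param error_rates validation-genotype error rates (0 = correct).
#' @param alpha blending weight.
#' @param training_error_rate rate for the training-genotype side run
#'   (`NULL` to skip).
#' @param n_replicates number of replicates (defaults to the config).
#' @param master_seed integer master seed.
#' @param output_dir if non-`NULL`, per-replicate artifacts
#'   (`pedigree.csv`, genotype/phenotype files, `solutions.csv`,
#'   `snp_effects.csv`, `ip_<scenario>.csv`) plus `summary.csv` and a JSON
#'   run manifest are written there.
#' @param apy,core_size use the APY inverse in the reduced run.
#' @param shared_loci perturb one shared locus set across candidates
#'   instead of independent sets (see [inject_errors()]).
#' @param solver,tol passed to the [ssgblup()] fits.
#' @param verbose log per-stage progress.
#' @return object of class `ip_experiment`: `reports` (per replicate x
#'   scenario statistics), `summary` (aggregated), `tables`, `mean_ip`,
#'   `mean_gebv`, `predictions` (long GEBV/IP per candidate), and the run
#'   manifest.
#' @export
run_experiment <- function(config = desk_profile(),
                           error_rates = c(0, 0.05, 0.10, 0.20),
                           alpha = 0.05, training_error_rate = 0.20,
                           n_replicates = NULL, master_seed = 1L,
                           output_dir = NULL, apy = FALSE, core_size = NULL,
                           shared_loci = FALSE, solver = "auto",
                           tol = 1e-8, verbose = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(n_replicates)) n_replicates <- config$n_replicates
  error_rates <- sort(error_rates)
  say <- function(...) if (verbose) message(sprintf(...))
  sigma2_a <- config$h2 * config$sigma2_p
  reports <- NULL
  ci_list <- list()
  preds <- list()
  mean_rows <- list()
  for (r in seq_len(n_replicates)) {
    t0 <- Sys.time()
    seed_r <- (master_seed + r) %% (.Machine$integer.max - 3000001L)
    say("replicate %d/%d: simulating population (seed %d)", r, n_replicates,
        seed_r)
    pop <- simulate_population(config, seed_r)
    say("  benchmark ssGBLUP (%d animals)", pop$n_animals)
    bench <- run_benchmark(pop, alpha = alpha, solver = solver, tol = tol)
    gebv_v <- attr(bench, "validation_gebv")
    say("  reduced ssGBLUP + back-solving")
    red <- run_reduced(pop, alpha = alpha, solver = solver, tol = tol,
                       apy = apy, core_size = core_size,
                       core_seed = seed_r + 900000L)
    eff <- snp_effects(red)
    geno_val <- pop_genotypes(pop, validation_ids(pop))
    ips <- run_scenarios(eff, geno_val, error_rates,
                         seed = seed_r + 1000000L, shared_loci = shared_loci)
    if (!is.null(training_error_rate) && training_error_rate > 0) {
      say("  training-error side run (rate %.2f)", training_error_rate)
      geno_t <- pop_genotypes(pop, training_ids(pop))
      geno_t_err <- inject_errors(geno_t, training_error_rate,
                                  seed = seed_r + 2000000L,
                                  shared_loci = shared_loci)
      # frozen tuning constants: the noisy genotypes flow into an existing
      # pipeline whose c and d were calibrated on the clean evaluation;
      # re-tuning on the noisy G would renormalize away the error signal
      red_te <- run_reduced(pop, training_genotypes = geno_t_err,
                            alpha = alpha, solver = solver, tol = tol,
                            tune = list(c = red$blend$c, d = red$blend$d))
      ips$training_error <- compute_ip(geno_val, snp_effects(red_te))
    }
    for (sc in names(ips)) {
      mean_rows[[length(mean_rows) + 1L]] <-
        data.frame(replicate = r, scenario = sc, mean_ip = mean(ips[[sc]]),
                   mean_gebv = mean(gebv_v))
      if (sc == "training_error") next   # directional side experiment only
      rep_row <- evaluate_predictions(gebv_v, ips[[sc]], sigma2_a = sigma2_a)
      ci_list[[length(ci_list) + 1L]] <- attr(rep_row, "ci")
      rep_row <- cbind(data.frame(replicate = r, scenario = sc), rep_row)
      reports <- rbind(reports, rep_row)
      preds[[length(preds) + 1L]] <-
        data.frame(id = as.integer(names(gebv_v)), replicate = r,
                   scenario = sc, gebv = as.numeric(gebv_v),
                   ip = as.numeric(ips[[sc]]))
    }
    if (!is.null(output_dir)) {
      rd <- file.path(output_dir, sprintf("replicate_%d", r))
      export_population(pop, rd)
      utils::write.csv(data.frame(id = names(bench$gebv), effect = "animal",
                                  solution = as.numeric(bench$gebv)),
                       file.path(rd, "solutions.csv"), row.names = FALSE)
      utils::write.csv(data.frame(locus_index = seq_along(eff),
                                  chromosome = pop$map$loci$chr[pop$map$snp_idx],
                                  position = pop$map$loci$pos_cM[pop$map$snp_idx],
                                  effect = as.numeric(eff)),
                       file.path(rd, "snp_effects.csv"), row.names = FALSE)
      for (sc in names(ips))
        utils::write.csv(data.frame(id = names(ips[[sc]]), scenario = sc,
                                    ip = as.numeric(ips[[sc]])),
                         file.path(rd, sprintf("ip_%s.csv", sc)),
                         row.names = FALSE)
    }
    say("  replicate done in %.1f s",
        as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }
  attr(reports, "ci_list") <- ci_list
  summary <- aggregate_replicates(reports)
  mean_ip <- do.call(rbind, mean_rows)
  out <- structure(list(config = config, alpha = alpha,
                        error_rates = error_rates,
                        training_error_rate = training_error_rate,
                        master_seed = master_seed,
                        n_replicates = n_replicates,
                        reports = reports, summary = summary,
                        tables = render_tables(summary),
                        mean_ip = mean_ip,
                        predictions = do.call(rbind, preds),
                        manifest = list(
                          package = "ipgblup",
                          version = as.character(utils::packageVersion("ipgblup")),
                          master_seed = master_seed, alpha = alpha,
                          error_rates = error_rates,
                          training_error_rate = training_error_rate,
                          n_replicates = n_replicates,
                          config = unclass(config))),
                   class = "ip_experiment")
  if (!is.null(output_dir)) {
    dir.create(file.path(output_dir, "results"), recursive = TRUE,
               showWarnings = FALSE)
    utils::write.csv(summary, file.path(output_dir, "results", "summary.csv"),
                     row.names = FALSE)
    utils::write.csv(out$predictions,
                     file.path(output_dir, "results", "predictions.csv"),
                     row.names = FALSE)
    jsonlite::write_json(out$manifest,
                         file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' @export
print.ip_experiment <- function(x, ...) {
  cat("Indirect-prediction genotyping-error experiment\n")
  cat(sprintf("  %d replicates, alpha = %.2f, scenarios: %s\n",
              x$n_replicates, x$alpha,
              paste(unique(x$reports$scenario), collapse = ", ")))
  cat("\nCorrelations and regression of benchmark GEBV on IP (mean ± SE):\n")
  print(x$tables$correlations, row.names = FALSE)
  cat("\nRMSE, standardized bias and variance ratio (mean ± SE):\n")
  print(x$tables$errors, row.names = FALSE)
  te <- x$mean_ip[x$mean_ip$scenario == "training_error", ]
  if (nrow(te)) {
    corr <- x$mean_ip[x$mean_ip$scenario == "correct", ]
    cat(sprintf(paste0("\nTraining-error side run: mean IP %.3f",
                       " vs %.3f with correct training genotypes\n"),
                mean(te$mean_ip), mean(corr$mean_ip)))
  }
  invisible(x)
}

#' Boxplots of benchmark GEBV and scenario indirect predictions
#'
#' @param x an `ip_experiment`.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.ip_experiment <- function(x, ...) {
  p <- x$predictions
  first <- p$scenario == p$scenario[1]
  vals <- c(list(GEBV = p$gebv[first]),
            split(p$ip, factor(p$scenario, levels = scenario_order(p$scenario))))
  graphics::boxplot(vals, ylab = "breeding value",
                    main = "Benchmark GEBV and indirect predictions", ...)
  invisible(x)
}
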