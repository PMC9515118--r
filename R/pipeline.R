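#' Configuration of a full analysis run
#'
#' Bundles the design, the data source (a generative population or a trial
#' file), the families to fit, the MCMC configuration and the seed. Every
#' stochastic stage derives its stream from `seed`, so a configuration
#' regenerates its report exactly.
#'
#' @param hyper A [group_hyper()] generative population (ignored when
#'   `data_path` is given).
#' @param n_subjects Number of simulated subjects.
#' @param data_path Optional path of a trial table to analyse instead of
#'   simulating.
#' @param outcome_sets Three gain outcome quadruples (see [build_session()]).
#' @param generating_family Family used to simulate choices.
#' @param families Families to fit and compare.
#' @param domain Domain entering the likelihood.
#' @param mcmc An [mcmc_config()].
#' @param ppc_samples Posterior samples for the predictive accuracy check.
#' @param seed Integer master seed.
#' @param output_dir Directory for artifacts; `NULL` disables writing.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(hyper = group_hyper(), n_subjects = 12L,
                       data_path = NULL,
                       outcome_sets = default_outcome_sets(),
                       generating_family = "kahneman_tversky",
                       families = c("linear", "kahneman_tversky", "prelec1"),
                       domain = "gain", mcmc = mcmc_config("test"),
                       ppc_samples = 500L, seed = 1L, output_dir = NULL) {
  families <- vapply(families, match_family, character(1), USE.NAMES = FALSE)
  structure(list(hyper = hyper, n_subjects = as.integer(n_subjects),
                 data_path = data_path, outcome_sets = outcome_sets,
                 generating_family = match_family(generating_family),
                 families = families, domain = domain, mcmc = mcmc,
                 ppc_samples = as.integer(ppc_samples),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

config_hash <- function(config) {
  payload <- config[setdiff(names(config), "output_dir")]
  payload$hyper <- unclass(payload$hyper)
  payload$mcmc <- unclass(payload$mcmc)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

stage_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                               sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) trials, fit every requested weighting family, compare
#' them by LOOIC/WAIC, run the posterior predictive accuracy check on the
#' selected model and build the stimulation-effect table. Artifacts (trial
#' table, posterior draws, JSON report) are written to
#' `config$output_dir` when set. Convergence warnings (split-Rhat > 1.01)
#' and Pareto-k flags are collected into the report, never swallowed.
#'
#' @param config A [run_config()].
#' @param verbose Log stage progress and timings.
#' @return A `"run_report"` list: `comparison`, `effects`, `ppc`,
#'   `diagnostics`, `provenance`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t_all <- proc.time()[["elapsed"]]
  hash <- config_hash(config)
  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  stage_log(verbose, "stage data: %s", hash)
  trials <- if (is.null(config$data_path)) {
    simulate_dataset(config$hyper, config$n_subjects, config$outcome_sets,
                     config$generating_family, seed = config$seed)
  } else read_trials(config$data_path)
  if (!is.null(out_dir))
    write_trials(trials, file.path(out_dir, "trials.tsv"))

  fits <- list()
  warnings_seen <- character(0)
  for (fam in config$families) {
    stage_log(verbose, "stage fit: %s", fam)
    t0 <- proc.time()[["elapsed"]]
    fit <- withCallingHandlers(
      fit_rdu(trials, fam, config$domain, config$mcmc,
              seed = config$seed + match(fam, weighting_families())),
      warning = function(w) {
        warnings_seen <<- c(warnings_seen, paste0(fam, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    grp <- group_names(fit)
    bad_rhat <- grp[!is.na(fit$diagnostics$rhat[grp]) &
                      fit$diagnostics$rhat[grp] > 1.01]
    if (length(bad_rhat))
      warnings_seen <- c(warnings_seen,
                         paste0(fam, ": split-Rhat > 1.01 for ",
                                paste(bad_rhat, collapse = ", ")))
    stage_log(verbose, "  fitted %s in %.1fs (%d params)", fam,
              proc.time()[["elapsed"]] - t0, length(dimnames(fit$draws)[[3]]))
    if (!is.null(out_dir))
      write_posterior(fit, file.path(out_dir, paste0("posterior_", fam, ".tsv")))
    fits[[fam]] <- fit
  }

  stage_log(verbose, "stage compare")
  comparison <- withCallingHandlers(
    compare_models(fits),
    warning = function(w) {
      warnings_seen <<- c(warnings_seen, paste0("compare: ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  selected <- comparison$selected

  stage_log(verbose, "stage ppc + effects (selected: %s)", selected)
  sel_fit <- fits[[selected]]
  ppc <- ppc_accuracy(sel_fit,
                      n_samples = min(config$ppc_samples,
                                      total_draws(config$mcmc)),
                      seed = config$seed)
  eff_fit <- if (selected != "linear") sel_fit else {
    nonlin <- setdiff(names(fits), "linear")
    if (length(nonlin)) fits[[nonlin[1]]] else NULL
  }
  effects <- if (is.null(eff_fit)) NULL else effect_table(eff_fit)

  diag_summary <- lapply(fits, function(f) {
    grp <- group_names(f)
    list(max_rhat_group = max(f$diagnostics$rhat[grp], na.rm = TRUE),
         min_ess_group = min(f$diagnostics$ess[grp], na.rm = TRUE),
         divergences = sum(vapply(f$sampler, function(s) s$divergences,
                                  numeric(1))))
  })

  report <- structure(list(
    comparison = comparison, selected = selected, effects = effects,
    ppc = ppc[c("median", "ci95")], diagnostics = diag_summary,
    warnings = warnings_seen, fits = fits, trials = trials,
    provenance = list(config_hash = hash, seed = config$seed,
                      families = config$families,
                      n_subjects = length(unique(trials$subject)),
                      n_trials = nrow(trials),
                      elapsed_s = proc.time()[["elapsed"]] - t_all)),
    class = "run_report")

  if (!is.null(out_dir)) {
    json <- report[c("selected", "ppc", "diagnostics", "warnings", "provenance")]
    json$comparison <- comparison$table
    json$effects <- effects
    writeLines(jsonlite::toJSON(json, auto_unbox = TRUE, digits = NA,
                                dataframe = "rows", force = TRUE,
                                pretty = TRUE),
               file.path(out_dir, "report.json"))
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %s selected; PPC median %.3f; hash %s\n",
              x$selected, x$ppc$median, x$provenance$config_hash))
  invisible(x)
}

#' Parameter-recovery experiment
#'
#' Repeatedly simulates a population from known hyperparameters, refits the
#' generating family and summarizes, per group-level parameter: bias and
#' RMSE of the posterior mean, and coverage of the 95% credible interval
#' over replicates. Also records the rank correlation between true and
#' recovered subject-level consistency parameters.
#'
#' @param config A [run_config()] whose `hyper` holds the generating truth.
#' @param n_replicates Number of simulate-and-refit replicates.
#' @param verbose Log per-replicate progress.
#' @return A `"recovery_report"`: per-parameter summary table, per-replicate
#'   details and the generating values.
#' @export
recovery_experiment <- function(config, n_replicates = 10L, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  fam <- config$generating_family
  tab <- param_table(fam)
  truth <- config$hyper$means[tab$name]
  reps <- vector("list", n_replicates)
  for (rep in seq_len(n_replicates)) {
    seed_r <- config$seed + 1000L * rep
    stage_log(verbose, "recovery replicate %d/%d (seed %d)",
              rep, n_replicates, seed_r)
    trials <- simulate_dataset(config$hyper, config$n_subjects,
                               config$outcome_sets, fam, seed = seed_r)
    fit <- suppressWarnings(
      fit_rdu(trials, fam, config$domain, config$mcmc, seed = seed_r,
              store_loglik = FALSE))
    per_par <- lapply(tab$name, function(nm) {
      smp <- as.vector(fit$draws[, , paste0("mu_", nm)])
      ci <- credible_interval(smp, 0.95)
      c(mean = mean(smp), lower = ci[[1]], upper = ci[[2]])
    })
    names(per_par) <- tab$name
    truth_subj <- attr(trials, "subject_params")
    tau_cols <- sprintf("tau0[%d]", seq_len(config$n_subjects))
    tau_hat <- vapply(tau_cols, function(p) mean(fit$draws[, , p]), numeric(1))
    reps[[rep]] <- list(params = per_par,
                        tau_rank_cor = stats::cor(truth_subj$tau0, tau_hat,
                                                  method = "spearman"))
  }
  summary <- do.call(rbind, lapply(tab$name, function(nm) {
    est <- vapply(reps, function(r) r$params[[nm]][["mean"]], numeric(1))
    lo <- vapply(reps, function(r) r$params[[nm]][["lower"]], numeric(1))
    hi <- vapply(reps, function(r) r$params[[nm]][["upper"]], numeric(1))
    tr <- truth[[nm]]
    data.frame(parameter = paste0("mu_", nm), truth = tr,
               bias = mean(est) - tr, rmse = sqrt(mean((est - tr)^2)),
               coverage95 = mean(lo <= tr & tr <= hi),
               excludes_zero = mean(lo > 0 | hi < 0),
               stringsAsFactors = FALSE)
  }))
  structure(list(summary = summary, replicates = reps, truth = truth,
                 tau_rank_cor = mean(vapply(reps, `[[`, numeric(1),
                                            "tau_rank_cor"))),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  print(x$summary, row.names = FALSE, digits = 3)
  cat(sprintf("mean subject-tau rank correlation: %.2f\n", x$tau_rank_cor))
  invisible(x)
}
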