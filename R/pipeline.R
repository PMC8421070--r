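#' Run configuration
#'
#' Bundles the choices a reproducible end-to-end run depends on. Cohort
#' sizes default to the experiment groups (16 for the multi-field
#' experiment, 10 for its generalization variant, 8 and 26 for the two
#' obstacle experiments). All defaults are serialized into the report for
#' provenance.
#'
#' @param experiment one of `"expt1"`, `"expt1_gen"`, `"expt2a"`,
#'   `"expt2b"`.
#' @param seed root integer seed.
#' @param n cohort size (experiment default when `NULL`).
#' @param ground_truth planning rule of the generator, `"po"` or `"ma"`.
#' @param dir_noise_sd movement-direction noise SD (deg; multi-field
#'   generator).
#' @param interval prediction-index interval convention: `"to_ton"` or
#'   `"to_t_resp"`.
#' @param schedule_scale fraction scaling the multi-field schedule trial
#'   counts (1 = the full 1305-trial paradigm).
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @return list of class `run_config`.
#' @export
run_config <- function(experiment = c("expt1", "expt1_gen", "expt2a",
                                      "expt2b"),
                       seed = 1L, n = NULL,
                       ground_truth = c("po", "ma"),
                       dir_noise_sd = 6,
                       interval = c("to_ton", "to_t_resp"),
                       schedule_scale = 1, out_dir = NULL) {
  experiment <- match.arg(experiment)
  ground_truth <- match.arg(ground_truth)
  interval <- match.arg(interval)
  if (is.null(n))
    n <- switch(experiment, expt1 = 16L, expt1_gen = 10L, expt2a = 8L,
                expt2b = 26L)
  if (n < 1) stop("cohort size must be at least 1")
  structure(list(experiment = experiment, seed = as.integer(seed),
                 n = as.integer(n), ground_truth = ground_truth,
                 dir_noise_sd = dir_noise_sd, interval = interval,
                 schedule_scale = schedule_scale, out_dir = out_dir),
            class = "run_config")
}

## scaled multi-field schedule
config_schedule <- function(config) {
  s <- config$schedule_scale
  ff_schedule(
    n_baseline_null = round(120 * s), n_baseline_2t = round(200 * s),
    n_baseline_1t = round(85 * s), n_training = round(500 * s),
    n_test_ff = round(300 * s), n_test_ec = round(50 * s),
    n_test_partial = round(50 * s),
    gen_probes = config$experiment == "expt1_gen")
}

#' Simulate an experiment from a configuration
#'
#' Dispatches to the multi-field or obstacle generator. When the config
#' has an `out_dir`, trial/summary CSV tables are written there.
#'
#' @param config a [run_config()] (or a list read by [read_config()]).
#' @return the generator output (see [simulate_ff_cohort()],
#'   [simulate_obstacle_cohort()]).
#' @export
simulate_experiment <- function(config) {
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  out <- if (config$experiment %in% c("expt1", "expt1_gen")) {
    simulate_ff_cohort(n = config$n, seed = config$seed,
                       schedule = config_schedule(config),
                       planning = config$ground_truth,
                       dir_noise_sd = config$dir_noise_sd)
  } else {
    simulate_obstacle_cohort(obstacle_cohort_spec(
      variant = config$experiment, n = config$n,
      ground_truth = config$ground_truth, seed = config$seed))
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (config$experiment %in% c("expt1", "expt1_gen")) {
      for (i in seq_along(out)) {
        keep <- Filter(function(tr) !is.null(tr$series), out[[i]]$trials)
        write_trials_csv(keep, file.path(
          config$out_dir, sprintf("trials_p%02d.csv", i)))
      }
    } else {
      write_summary_csv(out$summary,
                        file.path(config$out_dir, "summary.csv"))
      utils::write.csv(out$trials,
                       file.path(config$out_dir, "trial_directions.csv"),
                       row.names = FALSE)
    }
  }
  out
}

#' Analyze an experiment and assemble a report
#'
#' Runs the analysis stage matching the configured experiment on
#' simulated (or imported) data and returns a machine-readable report
#' embedding the config and seed. Obstacle experiments get the four
#' safety-margin model fits, the direction-space prediction index, and
#' both individuation fits with partial R-squared values; multi-field
#' experiments get the force-profile prediction indices. The report is
#' written as JSON when the config has an `out_dir`.
#'
#' @param config a [run_config()].
#' @param data output of [simulate_experiment()]; regenerated from the
#'   config when `NULL`. For obstacle experiments a summary data.frame is
#'   also accepted.
#' @param gen_fit optional generalization fit used to refine multi-field
#'   predictions.
#' @return report list.
#' @export
analyze_experiment <- function(config, data = NULL, gen_fit = NULL) {
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  if (is.null(data)) data <- simulate_experiment(config)
  base <- list(config = unclass(config)[!vapply(unclass(config), is.null,
                                                TRUE)],
               package_version = as.character(
                 utils::packageVersion("reachplan")))
  if (config$experiment %in% c("expt1", "expt1_gen")) {
    if (config$experiment == "expt1_gen") {
      curve <- generalization_curve(data)
      fit <- fit_generalization(curve$theta, curve$ac)
      report <- c(base, list(
        generalization = c(as.list(fit$params),
                           r_squared = fit$r_squared)))
    } else {
      res <- analyze_ff_cohort(data, gen_fit = gen_fit)
      report <- c(base, list(
        pi_ton = res$pi_ton$pi, pi_tresp = res$pi_tresp$pi,
        t_resp = res$t_resp,
        adaptation = as.list(stats::setNames(
          stats::aggregate(ac ~ target, res$adaptation, mean)$ac,
          c("left", "center", "right")))))
    }
  } else {
    summary <- if (is.data.frame(data)) data else data$summary
    fits <- list(
      MA_baseline = fit_safety_margin(summary, "ma", refined = FALSE),
      PO_baseline = fit_safety_margin(summary, "po", refined = FALSE),
      MA_refined = fit_safety_margin(summary, "ma", refined = TRUE),
      PO_refined = fit_safety_margin(summary, "po", refined = TRUE))
    dpi <- direction_prediction_index(summary)
    ind1 <- fit_individuation(summary, "one")
    ind3 <- fit_individuation(summary, "three")
    partial <- lapply(stats::setNames(nm = c("mu1A", "sigma2", "sigma1A")),
                      function(v) partial_r2(ind3, v)$partial_r2)
    report <- c(base, list(
      models = lapply(fits, function(f) list(
        weight = f$weight, prediction = f$prediction, mse = f$mse,
        mse_sem = f$mse_sem, n = f$n)),
      prediction_index = dpi$pi,
      variability_ratio = variability_ratio(summary),
      individuation = list(
        one = c(as.list(coef(ind1)), r_squared = ind1$r_squared),
        three = c(as.list(coef(ind3)), r_squared = ind3$r_squared),
        partial_r2 = partial)))
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report_json(report, file.path(config$out_dir, "report.json"))
  }
  report
}
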