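#' Write trials to a long CSV table
#'
#' One row per sample with the trial metadata repeated: `participant,
#' trial, epoch, type, target, ff_k, ff_B, clamp, obstacle, t, x, y, vx,
#' vy, f_lat`. Trials without a time series contribute a single row with
#' `NA` sample columns so that metadata round-trips.
#'
#' @param trials list of [reach_trial()]s.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_trials_csv <- function(trials, path) {
  blocks <- lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    meta <- cbind(trial_meta(tr)[1], trial = i, trial_meta(tr)[-1])
    if (is.null(tr$series)) {
      cbind(meta, t = NA_real_, x = NA_real_, y = NA_real_,
            vx = NA_real_, vy = NA_real_, f_lat = NA_real_)
    } else {
      cbind(meta[rep(1, nrow(tr$series)), ], tr$series)
    }
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read trials from a long CSV table
#'
#' Inverse of [write_trials_csv()]. Rows are validated for the expected
#' schema; violations are reported with the offending row numbers.
#'
#' @param path CSV path.
#' @param sample_rate sampling rate of the stored series (Hz).
#' @return list of [reach_trial()]s.
#' @export
read_trials_csv <- function(path, sample_rate = 200) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("participant", "trial", "epoch", "type", "target",
                "ff_k", "ff_B", "clamp", "obstacle", "t", "x", "y",
                "vx", "vy", "f_lat")
  missing <- setdiff(required, names(d))
  if (length(missing) > 0)
    stop("trial CSV is missing columns: ", paste(missing, collapse = ", "))
  bad <- which(!d$type %in% c("one_target", "two_target"))
  if (length(bad) > 0)
    stop("invalid trial type at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  lapply(split(d, factor(d$trial, levels = unique(d$trial))), function(b) {
    first <- b[1, ]
    ser <- NULL
    if (nrow(b) > 1 || is.finite(first$t))
      ser <- b[, c("t", "x", "y", "vx", "vy", "f_lat")]
    ff <- if (is.finite(first$ff_B) || first$clamp != "none")
      ff_condition(B = ifelse(is.finite(first$ff_B), first$ff_B, 0),
                   k = ifelse(is.finite(first$ff_k), first$ff_k, 0L),
                   clamp = first$clamp)
    else NULL
    reach_trial(
      participant = first$participant, epoch = first$epoch,
      trial_type = first$type,
      target_set = if (first$type == "two_target") c(-30, 30)
      else first$target,
      cued_target = first$target, ff = ff,
      obstacle_side = first$obstacle, sample_rate = sample_rate,
      movement_time = first$movement_time %||% NA_real_, series = ser)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read obstacle cohort summaries
#'
#' Summary tables carry one row per participant with columns
#' `participant, variant, mu1A, mu1B, sigma1A, sigma2, mu2` (optionally
#' `mu2_free`, `n_trials`). Reading validates the schema and the
#' positivity of the variability columns, naming offending rows.
#'
#' @param summary summary data.frame.
#' @param path CSV path.
#' @return the path ([write_summary_csv()]) or the validated data.frame.
#' @export
write_summary_csv <- function(summary, path) {
  utils::write.csv(summary, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary_csv
#' @export
read_summary_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("participant", "variant", "mu1A", "mu1B", "sigma1A",
                "sigma2", "mu2")
  missing <- setdiff(required, names(d))
  if (length(missing) > 0)
    stop("summary CSV is missing columns: ",
         paste(missing, collapse = ", "))
  bad <- which(!is.finite(d$sigma1A) | d$sigma1A <= 0 |
                 !is.finite(d$sigma2) | d$sigma2 <= 0)
  if (length(bad) > 0)
    stop("non-positive direction SD at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!d$variant %in% c("expt2a", "expt2b"))
  if (length(bad) > 0)
    stop("unknown variant at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  d
}

#' Import externally supplied summary tables
#'
#' Adapter for user-supplied data: reads every `*.csv` in a directory as a
#' summary table (see [read_summary_csv()]) and returns the pooled rows
#' split by experiment variant. Nothing is ever downloaded.
#'
#' @param dir directory containing summary CSV files.
#' @return named list of summary data.frames, one per variant present.
#' @export
import_external <- function(dir) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  if (length(files) == 0) stop("no CSV files found in ", dir)
  all <- do.call(rbind, lapply(files, read_summary_csv))
  split(all, all$variant)
}

#' Read a run configuration file
#'
#' JSON configs are read with jsonlite; `.yaml`/`.yml` configs require the
#' yaml package.
#'
#' @param path config file path.
#' @return named list.
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Write a machine-readable analysis report
#'
#' Serializes a report list (results plus the config and seed that
#' produced them) as JSON. Numbers are written at full precision; equal
#' configs give byte-identical reports.
#'
#' @param report named list.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
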