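# End-to-end drivers: simulate -> preprocess -> fit -> bootstrap -> report,
# and the reproduction driver for externally supplied trial-level data.

#' Group-mean cycle series from a trial table
#'
#' @param trials Preprocessed trial table (see [preprocess_cohort()]).
#' @return A list: `mean` (group-mean baseline-corrected deviation per
#'   cycle), `matrix` (subjects x cycles), `n_subjects`.
#' @export
group_cycle_series <- function(trials) {
  m <- cycle_matrix(cycle_average(trials))
  list(mean = colMeans(m, na.rm = TRUE), matrix = m,
       n_subjects = nrow(m))
}

#' Sequential fit of the Independent Error model
#'
#' Stage 1 fits the SPE-only process to the TPE-free group's mean cycle
#' series; stage 2 freezes those estimates and fits the TPE process to the
#' TPE-exposed group.
#'
#' @param series_no_tpe,series_tpe Group-mean cycle series of the TPE-free
#'   and TPE-exposed groups.
#' @param drive_no_tpe,drive_tpe Their drive data frames.
#' @param config A [fit_config()].
#' @return A list with `stage1` and `stage2` `"reach_fit"` objects.
#' @export
sequential_fit_independent <- function(series_no_tpe, series_tpe,
                                       drive_no_tpe, drive_tpe,
                                       config = fit_config()) {
  stage1 <- fit_spe_only(series_no_tpe, drive_no_tpe, config)
  stage2 <- fit_independent_stage2(series_tpe, drive_tpe, stage1$params,
                                   config)
  list(stage1 = stage1, stage2 = stage2)
}

#' Sequential fit of the Interaction model
#'
#' Stage 1 fits the dynamics with gains pinned at 1 to the TPE-exposed
#' group (where the gains are inert by assumption); stage 2 freezes the
#' dynamics and estimates the gains from the TPE-free group.
#'
#' @param series_tpe,series_no_tpe Group-mean cycle series of the
#'   TPE-exposed and TPE-free groups.
#' @param drive_tpe,drive_no_tpe Their drive data frames.
#' @param config A [fit_config()].
#' @return A list with `stage1` and `stage2` `"reach_fit"` objects.
#' @export
sequential_fit_interaction <- function(series_tpe, series_no_tpe,
                                       drive_tpe, drive_no_tpe,
                                       config = fit_config()) {
  stage1 <- fit_interaction(series_tpe, drive_tpe, config)
  stage2 <- fit_interaction(series_no_tpe, drive_no_tpe, config,
                            frozen = stage1$params, estimate_gains = TRUE)
  list(stage1 = stage1, stage2 = stage2)
}

#' Parameter-recovery run on a synthetic cohort
#'
#' Generates a raw cohort under the given schedule and generator
#' configuration, runs the full kinematic pipeline, fits the generating
#' model's protocol to the group-mean cycle series, and reports truth
#' against estimates (optionally with bootstrap CIs). When the generator
#' includes a strategic re-aim (`strategy_plus_spe`), the known strategic
#' component is subtracted from the deviations before fitting, so the fit
#' targets the implicit process the parameters describe — the standard
#' move in a recovery study, where ground truth is available by
#' construction.
#'
#' @param schedule A `"reach_schedule"`.
#' @param gen_config A [generator_config()].
#' @param fit_cfg A [fit_config()].
#' @param n_boot Bootstrap resamples for parameter CIs (0 to skip).
#' @param boot_seed Seed for the bootstrap.
#' @return A list of class `"recovery_report"`: cohort seed, truth,
#'   estimates, fit, exclusion fraction, and optional `ci` data frame.
#' @export
run_recovery <- function(schedule, gen_config, fit_cfg = fit_config(),
                         n_boot = 0L, boot_seed = 1L) {
  cohort <- generate_raw_trials(schedule, gen_config)
  trials <- preprocess_cohort(cohort)
  # remove the known strategic re-aim so the fit sees only the implicit
  # state (identical across subjects: the aim policy is deterministic)
  strategic <- aim_sequence(schedule, gen_config$aim_policy,
                            strategy_lag = gen_config$strategy_lag)
  offset <- ifelse(strategic$strategy, schedule$jump_deg, 0)
  trials$hand_dev_bc_deg <- trials$hand_dev_bc_deg - offset[trials$trial]
  series <- group_cycle_series(trials)
  drive <- cohort$drive
  protocol <- switch(gen_config$generating_model,
                     spe_only = , strategy_plus_spe = "spe_only",
                     stop("run_recovery supports SPE-only generating ",
                          "models; use the fitting functions directly ",
                          "for the richer protocols", call. = FALSE))
  fit <- fit_spe_only(series$mean, drive, fit_cfg)
  truth <- gen_config$params[names(fit$params)]
  report <- list(schedule = c(attr(schedule, "experiment"),
                              attr(schedule, "group")),
                 seed = gen_config$seed,
                 truth = truth,
                 estimates = fit$params,
                 error = fit$params - truth,
                 r2 = fit$r2, rmse = fit$rmse,
                 exclusion_fraction = attr(trials, "exclusion_fraction"),
                 fit = fit)
  if (n_boot > 0) {
    report$ci <- bootstrap_parameter_ci(series$matrix, protocol, drive,
                                        fit_cfg, n_boot = n_boot,
                                        seed = boot_seed)
  }
  class(report) <- "recovery_report"
  report
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %s/%s (seed %d)\n",
              x$schedule[1], x$schedule[2], x$seed))
  for (p in names(x$estimates))
    cat(sprintf("  %-12s truth %8.4f  estimate %8.4f  error %+8.4f\n",
                p, x$truth[[p]], x$estimates[[p]], x$error[[p]]))
  cat(sprintf("  R2 = %.3f, RMSE = %.3f, excluded = %.2f%%\n",
              x$r2, x$rmse, 100 * x$exclusion_fraction))
  invisible(x)
}

# Column aliases accepted when loading external trial-level tables.
.column_aliases <- list(
  subject = c("subject", "subj", "id", "participant", "sub"),
  group = c("group", "condition", "grp"),
  trial = c("trial", "trial_no", "trialnum", "trial_index"),
  hand_dev_deg = c("hand_dev_deg", "hand_deviation", "hand_angle",
                   "dev_deg", "hand_dev", "deviation"),
  rt_ms = c("rt_ms", "rt", "reaction_time", "rt_msec")
)

#' Load an external trial-level table with explicit column mapping
#'
#' Maps the file's columns onto the package's trial-table layout using
#' `column_map` (names = package columns, values = file columns); common
#' aliases are tried for anything not mapped explicitly. Block and cycle
#' labels are taken from the supplied schedule by trial index, and the
#' schedule's sign normalization (for clockwise-perturbation groups) is
#' applied to the deviations.
#'
#' @param path CSV file path.
#' @param schedule A `"reach_schedule"` describing the design the data
#'   came from.
#' @param column_map Named character vector of explicit column mappings.
#' @return A trial table suitable for [baseline_correct()] /
#'   [cycle_average()].
#' @export
read_trial_table <- function(path, schedule, column_map = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  pick <- function(target) {
    if (target %in% names(column_map)) {
      col <- column_map[[target]]
      if (!col %in% names(raw))
        stop("mapped column '", col, "' for '", target,
             "' not present in ", path, call. = FALSE)
      return(raw[[col]])
    }
    hit <- intersect(.column_aliases[[target]], tolower(names(raw)))
    if (!length(hit))
      stop("cannot map column '", target, "'; supply column_map",
           call. = FALSE)
    raw[[which(tolower(names(raw)) == hit[1])[1]]]
  }
  out <- data.frame(subject = pick("subject"),
                    trial = pick("trial"),
                    hand_dev_deg = pick("hand_dev_deg"),
                    rt_ms = tryCatch(pick("rt_ms"),
                                     error = function(e) NA_real_))
  out$block <- schedule$block[out$trial]
  out$cycle <- schedule$cycle[out$trial]
  if (isTRUE(attr(schedule, "sign_flip")))
    out$hand_dev_deg <- -out$hand_dev_deg
  out$excluded <- is.na(out$hand_dev_deg)
  out$reason <- ifelse(out$excluded, "no_movement", "none")
  apply_exclusions(out)
}

#' Reproduce a sequential model fit on externally supplied data
#'
#' Runs the two-stage fit protocol for the chosen experiment and model on
#' trial-level hand-deviation tables (one file per group), including
#' bootstrap CIs for the stage-2 parameters.
#'
#' @param paths Named character vector of CSV paths, one per group (names
#'   are the group labels of the experiment).
#' @param experiment `"E1"` or `"E3"`.
#' @param model `"independent"` or `"interaction"`.
#' @param column_map Passed to [read_trial_table()].
#' @param fit_cfg A [fit_config()]; the drive bound defaults to the
#'   experiment's maximum error angle (10 deg for E1, 30 deg for E3).
#' @param n_boot Bootstrap resamples (0 to skip).
#' @param boot_seed Seed for the bootstrap.
#' @return A list: `stage1`, `stage2` fits, group series, and optional
#'   `ci`.
#' @export
run_reproduction <- function(paths, experiment = c("E1", "E3"),
                             model = c("independent", "interaction"),
                             column_map = character(),
                             fit_cfg = NULL, n_boot = 10000L,
                             boot_seed = 1L) {
  experiment <- match.arg(experiment)
  model <- match.arg(model)
  if (experiment == "E3" && model == "independent")
    stop("the Independent Error protocol is defined for E1", call. = FALSE)
  if (is.null(fit_cfg))
    fit_cfg <- fit_config(drive_bound_deg = if (experiment == "E1") 10
                          else 30)
  groups <- if (experiment == "E1") c("Hit", "Miss")
            else c("Clamp", "ClampJump")
  if (!all(groups %in% names(paths)))
    stop("paths must be named with groups: ",
         paste(groups, collapse = ", "), call. = FALSE)
  dat <- lapply(groups, function(g) {
    sched <- build_schedule(experiment, g)
    trials <- read_trial_table(paths[[g]], sched, column_map)
    trials <- baseline_correct(trials)
    list(schedule = sched, drive = drive_sequence(sched),
         series = group_cycle_series(trials))
  })
  names(dat) <- groups

  if (model == "independent") {
    # E1: stage 1 on Hit (no TPE), stage 2 on Miss.
    fits <- sequential_fit_independent(dat$Hit$series$mean,
                                       dat$Miss$series$mean,
                                       dat$Hit$drive, dat$Miss$drive,
                                       fit_cfg)
    boot <- list(matrix = dat$Miss$series$matrix, drive = dat$Miss$drive,
                 protocol = "independent_stage2")
  } else {
    tpe_grp <- if (experiment == "E1") "Miss" else "Clamp"
    fre_grp <- if (experiment == "E1") "Hit" else "ClampJump"
    fits <- sequential_fit_interaction(dat[[tpe_grp]]$series$mean,
                                       dat[[fre_grp]]$series$mean,
                                       dat[[tpe_grp]]$drive,
                                       dat[[fre_grp]]$drive, fit_cfg)
    boot <- list(matrix = dat[[fre_grp]]$series$matrix,
                 drive = dat[[fre_grp]]$drive,
                 protocol = "interaction_gains")
  }
  out <- list(experiment = experiment, model = model,
              stage1 = fits$stage1, stage2 = fits$stage2,
              series = lapply(dat, function(d) d$series$mean))
  if (n_boot > 0) {
    out$ci <- bootstrap_parameter_ci(boot$matrix, boot$protocol,
                                     boot$drive, fit_cfg,
                                     frozen = fits$stage1$params,
                                     n_boot = n_boot, seed = boot_seed)
  }
  out
}

#' Serialize a fit or report to JSON
#'
#' @param x A `"reach_fit"`, bootstrap CI data frame, or recovery report.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_report_json <- function(x, path) {
  if (inherits(x, "reach_fit")) {
    x <- list(model = x$model, params = as.list(x$params),
              frozen = as.list(x$frozen), r2 = x$r2, rmse = x$rmse,
              objective = x$objective)
  } else if (inherits(x, "recovery_report")) {
    x <- list(schedule = x$schedule, seed = x$seed,
              truth = as.list(x$truth), estimates = as.list(x$estimates),
              r2 = x$r2, rmse = x$rmse,
              exclusion_fraction = x$exclusion_fraction,
              ci = x$ci)
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
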