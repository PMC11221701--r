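# Box-constrained least-squares fitting of the learning models to
# cycle-averaged hand deviations, the two sequential fit protocols, and
# participant-resampling bootstrap confidence intervals.

#' Fitting configuration
#'
#' Retention factors are constrained to \[0, 1\] and lumped drives to
#' \[0, `drive_bound_deg`\]; the drive bound is the maximum error angle the
#' clamp can impose in the experiment (10 deg for the 10-deg-jump designs,
#' 30 deg for the 30-deg clamp). Gain bounds default to \[0, 3\]. The
#' optimizer is restarted from `n_starts` seeded uniform points inside the
#' box (plus the box midpoint) and the best objective wins.
#'
#' @param drive_bound_deg Upper bound for lumped drive parameters (deg).
#' @param gain_bounds Length-2 bounds for the Interaction-model gains.
#' @param n_starts Number of random multi-starts.
#' @param tolerance Convergence tolerance passed to the optimizer
#'   (`factr`-style relative tolerance on the objective).
#' @param seed Integer seed for the random starts.
#' @return A list of class `"fit_config"`.
#' @export
fit_config <- function(drive_bound_deg = 10, gain_bounds = c(0, 3),
                       n_starts = 20L, tolerance = 1e-9, seed = 1L) {
  stopifnot(drive_bound_deg > 0, length(gain_bounds) == 2L,
            gain_bounds[1] < gain_bounds[2], n_starts >= 1L, tolerance > 0)
  structure(list(drive_bound_deg = drive_bound_deg,
                 gain_bounds = gain_bounds,
                 n_starts = as.integer(n_starts),
                 tolerance = tolerance,
                 seed = as.integer(seed)),
            class = "fit_config")
}

# Lean model recursions used inside objective functions (the exported
# simulate_* wrappers add validation and tidy output on top of these).
.rec_spe <- function(A, B, spe) {
  n <- length(spe)
  x <- numeric(n)
  for (k in seq_len(n - 1L)) x[k + 1L] <- A * x[k] + B * spe[k]
  x
}

.rec_interaction <- function(A, B, G_A, G_B, spe, tpe) {
  n <- length(spe)
  x <- numeric(n)
  for (k in seq_len(n - 1L)) {
    if (tpe[k] == 1)
      x[k + 1L] <- A * x[k] + B * spe[k]
    else
      x[k + 1L] <- G_A * A * x[k] + G_B * B * spe[k]
  }
  x
}

# Multi-start L-BFGS-B on a box: the first start is `init` (the box
# midpoint if not given), the remaining n_starts - 1 are seeded uniform
# draws inside the box. Returns the best optim() result.
.ls_optimize <- function(objective, lower, upper, config, init = NULL) {
  k <- length(lower)
  n_rand <- max(config$n_starts - 1L, 0L)
  starts <- withr::with_seed(config$seed, {
    m <- matrix(stats::runif(n_rand * k), ncol = k)
    sweep(sweep(m, 2, upper - lower, "*"), 2, lower, "+")
  })
  if (is.null(init)) init <- (lower + upper) / 2
  starts <- rbind(pmin(pmax(init, lower), upper), starts)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[i, ], objective, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = config$tolerance /
                                    .Machine$double.eps)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("optimizer failed at every start", call. = FALSE)
  best
}

.masked_sse <- function(observed, predicted, use) {
  sum((observed[use] - predicted[use])^2)
}

.fit_use_idx <- function(observed, drive) {
  if (length(observed) != nrow(drive))
    stop("observed series and drive have different cycle counts",
         call. = FALSE)
  use <- drive$fit_mask == 1 & !is.na(observed)
  if (!any(use)) stop("no cycles available for fitting", call. = FALSE)
  use
}

.new_fit <- function(model, params, frozen, observed, drive, predicted,
                     objective, use) {
  gof <- goodness_of_fit(observed, predicted, use)
  structure(list(model = model, params = params, frozen = frozen,
                 observed = observed, predicted = predicted,
                 fit_mask = use, objective = objective,
                 r2 = gof$r2, rmse = gof$rmse),
            class = "reach_fit")
}

#' @export
print.reach_fit <- function(x, ...) {
  cat(sprintf("<reach_fit> model = %s\n", x$model))
  p <- paste(sprintf("%s = %.4f", names(x$params), x$params),
             collapse = ", ")
  cat("  free:  ", p, "\n", sep = "")
  if (length(x$frozen))
    cat("  frozen:", paste(sprintf("%s = %.4f", names(x$frozen), x$frozen),
                           collapse = ", "), "\n")
  cat(sprintf("  R2 = %.4f, RMSE = %.4f, SSE = %.6g over %d cycles\n",
              x$r2, x$rmse, x$objective, sum(x$fit_mask)))
  invisible(x)
}

#' Fit the SPE-only learning process
#'
#' Estimates the retention factor `A_spe` and the lumped drive
#' `B_spe_drive` of the single-process learner by least squares on the
#' masked cycle series (baseline, learning and no-feedback washout cycles;
#' feedback-washout cycles are excluded because the clamp is removed there
#' and the error is no longer constant).
#'
#' @param observed Numeric vector: baseline-corrected group-mean hand
#'   deviation per cycle (NA allowed; such cycles are skipped).
#' @param drive Drive data frame from [drive_sequence()].
#' @param config A [fit_config()].
#' @param init Optional optimizer start `(A_spe, B_spe_drive)`; used as
#'   the first multi-start point.
#' @return An object of class `"reach_fit"`.
#' @export
fit_spe_only <- function(observed, drive, config = fit_config(),
                         init = NULL) {
  use <- .fit_use_idx(observed, drive)
  spe <- drive$spe_on
  obj <- function(p)
    .masked_sse(observed, .rec_spe(p[1], p[2], spe), use)
  best <- .ls_optimize(obj, c(0, 0), c(1, config$drive_bound_deg), config,
                       init = init)
  params <- c(A_spe = best$par[1], B_spe_drive = best$par[2])
  pred <- simulate_spe(params[1], params[2], drive)
  .new_fit("spe_only", params, numeric(0), observed, drive, pred,
           best$value, use)
}

#' Fit the TPE process of the Independent Error model (stage 2)
#'
#' With the SPE-process parameters frozen at values estimated from a
#' TPE-free group, estimates `A_tpe` and `B_tpe_drive` of the additive TPE
#' process from the net output of a group that experienced TPEs.
#'
#' @param observed Group-mean cycle series of the TPE-exposed group.
#' @param drive Drive data frame from [drive_sequence()].
#' @param frozen Named numeric with `A_spe` and `B_spe_drive`.
#' @param config A [fit_config()].
#' @param init Optional optimizer start `(A_tpe, B_tpe_drive)`.
#' @return An object of class `"reach_fit"`.
#' @export
fit_independent_stage2 <- function(observed, drive, frozen,
                                   config = fit_config(), init = NULL) {
  stopifnot(all(c("A_spe", "B_spe_drive") %in% names(frozen)))
  use <- .fit_use_idx(observed, drive)
  # The frozen SPE process does not depend on the free parameters.
  x_spe <- .rec_spe(frozen[["A_spe"]], frozen[["B_spe_drive"]],
                    drive$spe_on)
  tpe <- drive$tpe_on
  obj <- function(p)
    .masked_sse(observed, x_spe + .rec_spe(p[1], p[2], tpe), use)
  best <- .ls_optimize(obj, c(0, 0), c(1, config$drive_bound_deg), config,
                       init = init)
  params <- c(A_tpe = best$par[1], B_tpe_drive = best$par[2])
  pred <- simulate_independent(frozen[["A_spe"]], frozen[["B_spe_drive"]],
                               params[1], params[2], drive)$x_net
  .new_fit("independent", params, frozen[c("A_spe", "B_spe_drive")],
           observed, drive, pred, best$value, use)
}

#' Fit the Interaction model (either stage of the sequential protocol)
#'
#' Stage 1 (`estimate_gains = FALSE`): fits `A_spe` and `B_spe_drive` with
#' both gains pinned at 1, on the group for which TPE-present cycles make
#' the gains inert. Stage 2 (`estimate_gains = TRUE`): freezes the stage-1
#' dynamics and estimates only the gains `G_A`, `G_B` applied on TPE-absent
#' cycles of the other group.
#'
#' @param observed Group-mean cycle series.
#' @param drive Drive data frame from [drive_sequence()].
#' @param config A [fit_config()].
#' @param frozen Named numeric with `A_spe`, `B_spe_drive` (required for
#'   stage 2).
#' @param estimate_gains Logical switching between the two stages.
#' @param init Optional optimizer start for the free parameters.
#' @return An object of class `"reach_fit"`.
#' @export
fit_interaction <- function(observed, drive, config = fit_config(),
                            frozen = NULL, estimate_gains = FALSE,
                            init = NULL) {
  use <- .fit_use_idx(observed, drive)
  spe <- drive$spe_on
  tpe <- drive$tpe_on
  if (!estimate_gains) {
    obj <- function(p)
      .masked_sse(observed, .rec_spe(p[1], p[2], spe), use)
    best <- .ls_optimize(obj, c(0, 0), c(1, config$drive_bound_deg),
                         config, init = init)
    params <- c(A_spe = best$par[1], B_spe_drive = best$par[2])
    pred <- simulate_interaction(params[1], params[2], 1, 1, drive)
    return(.new_fit("interaction_stage1", params, numeric(0),
                    observed, drive, pred, best$value, use))
  }
  if (is.null(frozen) ||
      !all(c("A_spe", "B_spe_drive") %in% names(frozen)))
    stop("estimate_gains = TRUE requires frozen A_spe and B_spe_drive",
         call. = FALSE)
  obj <- function(p)
    .masked_sse(observed,
                .rec_interaction(frozen[["A_spe"]],
                                 frozen[["B_spe_drive"]],
                                 p[1], p[2], spe, tpe), use)
  gb <- config$gain_bounds
  best <- .ls_optimize(obj, c(gb[1], gb[1]), c(gb[2], gb[2]), config,
                       init = init)
  params <- c(G_A = best$par[1], G_B = best$par[2])
  pred <- simulate_interaction(frozen[["A_spe"]], frozen[["B_spe_drive"]],
                               params[1], params[2], drive)
  .new_fit("interaction_gains", params, frozen[c("A_spe", "B_spe_drive")],
           observed, drive, pred, best$value, use)
}

#' Goodness of fit of a predicted trace
#'
#' `r2 = 1 - SSres/SStot` with the total sum of squares taken about the
#' observed mean, and `rmse = sqrt(SSres / N)`, both over the cycles in
#' `use` (by default all non-missing cycles).
#'
#' @param observed,predicted Numeric cycle series of equal length.
#' @param use Logical mask of cycles to score.
#' @return A list with elements `r2`, `rmse` and `n`. `r2` is `NA` (with a
#'   warning) when the observed series has zero variance.
#' @export
goodness_of_fit <- function(observed, predicted,
                            use = !is.na(observed)) {
  stopifnot(length(observed) == length(predicted))
  o <- observed[use]; p <- predicted[use]
  if (length(o) < 2) stop("need at least 2 cycles", call. = FALSE)
  ss_res <- sum((o - p)^2)
  ss_tot <- sum((o - mean(o))^2)
  r2 <- if (ss_tot == 0) {
    warning("observed series has zero variance; R^2 undefined")
    NA_real_
  } else 1 - ss_res / ss_tot
  list(r2 = r2, rmse = sqrt(ss_res / length(o)), n = length(o))
}

#' Bootstrap confidence intervals for fitted parameters
#'
#' Resamples participants with replacement, recomputes the group-mean cycle
#' series, refits the requested protocol, and returns percentile 95%
#' intervals for each free parameter. Frozen stage-1 parameters are held at
#' their full-sample point estimates throughout. Bootstrap refits use a
#' reduced number of random starts (`n_starts_boot`); the low-dimensional
#' box-constrained objective is smooth enough that this does not change the
#' optimum found.
#'
#' @param subject_cycles Numeric matrix, one row per subject, one column
#'   per cycle (baseline-corrected deviations).
#' @param protocol One of `"spe_only"`, `"independent_stage2"`,
#'   `"interaction_stage1"`, `"interaction_gains"`.
#' @param drive Drive data frame from [drive_sequence()].
#' @param config A [fit_config()].
#' @param frozen Frozen parameters required by the stage-2 protocols.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed; results are deterministic given it.
#' @param n_starts_boot Multi-start count used inside the bootstrap loop.
#' @return A data frame with one row per free parameter: parameter,
#'   estimate, lo95, hi95, n_boot, seed.
#' @export
bootstrap_parameter_ci <- function(subject_cycles, protocol, drive,
                                   config = fit_config(), frozen = NULL,
                                   n_boot = 10000L, seed = 1L,
                                   n_starts_boot = 3L) {
  stopifnot(is.matrix(subject_cycles), nrow(subject_cycles) >= 2L)
  if (n_boot < 1) stop("n_boot must be >= 1", call. = FALSE)
  fit_one <- function(series, cfg, init = NULL) {
    switch(protocol,
           spe_only = fit_spe_only(series, drive, cfg, init = init),
           independent_stage2 =
             fit_independent_stage2(series, drive, frozen, cfg,
                                    init = init),
           interaction_stage1 =
             fit_interaction(series, drive, cfg, init = init),
           interaction_gains =
             fit_interaction(series, drive, cfg, frozen = frozen,
                             estimate_gains = TRUE, init = init),
           stop("unknown protocol: ", protocol, call. = FALSE))
  }
  point <- fit_one(colMeans(subject_cycles, na.rm = TRUE), config)
  n_sub <- nrow(subject_cycles)
  boot_cfg <- config
  boot_cfg$n_starts <- as.integer(n_starts_boot)
  draws <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n_sub, n_sub, replace = TRUE)
      series <- colMeans(subject_cycles[idx, , drop = FALSE], na.rm = TRUE)
      cfg_b <- boot_cfg
      cfg_b$seed <- config$seed + b
      fit_one(series, cfg_b, init = unname(point$params))$params
    }, numeric(length(point$params)))
  })
  draws <- matrix(draws, nrow = length(point$params))
  ci <- apply(draws, 1, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE)
  data.frame(parameter = names(point$params),
             estimate = unname(point$params),
             lo95 = ci[1, ], hi95 = ci[2, ],
             n_boot = as.integer(n_boot), seed = as.integer(seed),
             row.names = NULL)
}
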