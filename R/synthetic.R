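# Synthetic cohorts with the statistical structure the analysis assumes:
# model-driven learning curves, per-trial aim policies, angular motor
# noise, and RT structure, at raw-trajectory and cycle-series resolution.

#' Configuration of the synthetic cohort generator
#'
#' @param generating_model Learning model producing the implicit state:
#'   `"none"`, `"spe_only"`, `"independent"`, `"interaction"`, or
#'   `"strategy_plus_spe"` (SPE-only implicit learning riding on top of a
#'   re-aiming strategy; pair with `aim_policy = "aim_jumped"`).
#' @param params Named numeric vector of generating parameters (`A_spe`,
#'   `B_spe_drive`, and for the richer models `A_tpe`, `B_tpe_drive`,
#'   `G_A`, `G_B`).
#' @param aim_policy Strategic aim on learning trials: `"aim_original"` or
#'   `"ignore_jump"` (original target), `"aim_jumped"` (jumped target).
#' @param angular_noise_sd Trial-level angular motor noise SD in degrees.
#' @param cycle_noise_sd Cycle-level noise SD in degrees (used by
#'   [generate_cycle_traces()]).
#' @param rt_base Median reaction time in ms.
#' @param rt_strategy_boost Extra median RT in ms on strategy trials
#'   (re-aiming is time-consuming).
#' @param rt_jitter_sdlog SD of the lognormal RT jitter (log scale).
#' @param strategy_lag Learning trials before the aim switch takes effect.
#' @param sampling_rate Tablet sampling rate in Hz.
#' @param movement_time Reach duration in seconds.
#' @param reach_extent Distance covered by the reach in cm (beyond the
#'   10 cm target distance so the crossing is observed).
#' @param n_subjects Cohort size.
#' @param seed Integer seed; the cohort is deterministic given it.
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(generating_model = "spe_only",
                             params = c(A_spe = 0.8184,
                                        B_spe_drive = 0.8441),
                             aim_policy = c("aim_original", "aim_jumped",
                                            "ignore_jump"),
                             angular_noise_sd = 3, cycle_noise_sd = 1.5,
                             rt_base = 300, rt_strategy_boost = 150,
                             rt_jitter_sdlog = 0.1, strategy_lag = 2L,
                             sampling_rate = 100, movement_time = 0.6,
                             reach_extent = 12, n_subjects = 15L,
                             seed = 1L) {
  aim_policy <- match.arg(aim_policy)
  stopifnot(angular_noise_sd >= 0, cycle_noise_sd >= 0, n_subjects >= 1L,
            sampling_rate > 20, movement_time > 0, reach_extent > 0)
  structure(list(generating_model = generating_model, params = params,
                 aim_policy = aim_policy,
                 angular_noise_sd = angular_noise_sd,
                 cycle_noise_sd = cycle_noise_sd, rt_base = rt_base,
                 rt_strategy_boost = rt_strategy_boost,
                 rt_jitter_sdlog = rt_jitter_sdlog,
                 strategy_lag = as.integer(strategy_lag),
                 sampling_rate = sampling_rate,
                 movement_time = movement_time,
                 reach_extent = reach_extent,
                 n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Implicit state trace per cycle under the generating model.
.generating_state <- function(model, params, drive) {
  p <- function(k) if (k %in% names(params)) params[[k]] else
    stop("generating params lack ", k, call. = FALSE)
  switch(model,
         none = numeric(nrow(drive)),
         spe_only = ,
         strategy_plus_spe =
           simulate_spe(p("A_spe"), p("B_spe_drive"), drive),
         independent =
           simulate_independent(p("A_spe"), p("B_spe_drive"),
                                p("A_tpe"), p("B_tpe_drive"),
                                drive)$x_net,
         interaction =
           simulate_interaction(p("A_spe"), p("B_spe_drive"),
                                p("G_A"), p("G_B"), drive),
         stop("unknown generating model: ", model, call. = FALSE))
}

#' Per-trial intended reach angles under an aim policy
#'
#' The intended angle of each trial is the strategic aim (the original
#' target for `aim_original` / `ignore_jump`; the jumped target for
#' `aim_jumped`, after `strategy_lag` learning trials) plus the implicit
#' learned state of that trial's cycle.
#'
#' @param schedule A `"reach_schedule"`.
#' @param policy Aim policy (see [generator_config()]).
#' @param state Implicit state per cycle in degrees (zeros if omitted).
#' @param strategy_lag Learning trials before the aim switch.
#' @return Data frame: trial, aim_deg (absolute intended angle), strategy
#'   (whether the strategic re-aim is active on the trial).
#' @export
aim_sequence <- function(schedule, policy, state = NULL,
                         strategy_lag = 0L) {
  stopifnot(inherits(schedule, "reach_schedule"))
  n_cycles <- nrow(schedule) / 10L
  if (is.null(state)) state <- numeric(n_cycles)
  stopifnot(length(state) == n_cycles)
  learning <- schedule$block == "learning"
  strategy <- logical(nrow(schedule))
  if (policy == "aim_jumped") {
    li <- which(learning)
    strategy[li[seq_along(li) > strategy_lag]] <- TRUE
  }
  aim <- schedule$target_dir_deg +
    ifelse(strategy, schedule$jump_deg, 0) +
    state[schedule$cycle]
  data.frame(trial = schedule$trial, aim_deg = aim, strategy = strategy)
}

#' Generate per-subject cycle series from a learning model
#'
#' Each subject's series is the model-generated state trace plus
#' independent Gaussian noise per cycle.
#'
#' @param model Generating model name (see [generator_config()]).
#' @param params Named generating parameters.
#' @param drive Drive data frame from [drive_sequence()].
#' @param cycle_noise_sd Per-cycle noise SD in degrees.
#' @param n_subjects Number of subjects.
#' @param seed Integer seed.
#' @return Subjects-by-cycles matrix; the noiseless trace and generating
#'   parameters are attached as attributes `"truth_trace"` and
#'   `"truth_params"`.
#' @export
generate_cycle_traces <- function(model, params, drive, cycle_noise_sd,
                                  n_subjects, seed = 1L) {
  trace <- .generating_state(model, params, drive)
  n_cyc <- length(trace)
  m <- withr::with_seed(seed, {
    noise <- matrix(stats::rnorm(n_subjects * n_cyc, 0, cycle_noise_sd),
                    nrow = n_subjects)
    sweep(noise, 2, trace, "+")
  })
  attr(m, "truth_trace") <- trace
  attr(m, "truth_params") <- params
  m
}

# Radial minimum-jerk position profile. The profile is placed so that the
# analytic 5%-of-peak speed crossing falls exactly at the programmed
# movement onset, making the programmed RT recoverable by the pipeline's
# onset rule.
.minjerk_tau05 <- (1 - sqrt(1 - sqrt(0.05))) / 2

.minjerk_radius <- function(t, onset_s, mt, extent) {
  tau <- (t - onset_s) / mt + .minjerk_tau05
  tau <- pmin(pmax(tau, 0), 1)
  extent * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
}

#' Generate a cohort of raw reach trajectories
#'
#' For every trial of every subject: a straight-line reach along the
#' intended angle (policy aim + implicit state + Gaussian angular motor
#' noise), with a minimum-jerk speed profile covering `reach_extent` cm,
#' sampled at `sampling_rate`. The go cue is at t = 0; the programmed
#' onset is `rt_base` (plus `rt_strategy_boost` on strategy trials) with
#' multiplicative lognormal jitter. All ground truth (per-trial aim,
#' programmed RT, strategy flag, generating parameters and state trace)
#' is stored with the cohort.
#'
#' @param schedule A `"reach_schedule"`.
#' @param config A [generator_config()].
#' @return A list of class `"synthetic_cohort"`: `schedule`, `config`,
#'   `state` (implicit trace per cycle), and `subjects`, each with
#'   `trajectories` (list of data frames t_s, x_cm, y_cm) and `truth`
#'   (trial, aim_deg, rt_ms, strategy).
#' @export
generate_raw_trials <- function(schedule, config) {
  stopifnot(inherits(schedule, "reach_schedule"),
            inherits(config, "generator_config"))
  drive <- drive_sequence(schedule)
  state <- .generating_state(config$generating_model, config$params, drive)
  aims <- aim_sequence(schedule, config$aim_policy, state,
                       config$strategy_lag)
  n_trials <- nrow(schedule)
  fs <- config$sampling_rate
  mt <- config$movement_time

  subjects <- withr::with_seed(config$seed, {
    lapply(seq_len(config$n_subjects), function(s) {
      ang_noise <- stats::rnorm(n_trials, 0, config$angular_noise_sd)
      rt_med <- config$rt_base +
        ifelse(aims$strategy, config$rt_strategy_boost, 0)
      rt_ms <- rt_med * exp(stats::rnorm(n_trials, 0,
                                         config$rt_jitter_sdlog))
      angle <- aims$aim_deg + ang_noise
      trajectories <- lapply(seq_len(n_trials), function(i) {
        onset_s <- rt_ms[i] / 1000
        t <- seq(0, onset_s + mt + 0.15, by = 1 / fs)
        r <- .minjerk_radius(t, onset_s, mt, config$reach_extent)
        data.frame(t_s = t,
                   x_cm = r * cos(angle[i] * pi / 180),
                   y_cm = r * sin(angle[i] * pi / 180))
      })
      list(trajectories = trajectories,
           truth = data.frame(trial = seq_len(n_trials),
                              aim_deg = angle, rt_ms = rt_ms,
                              strategy = aims$strategy))
    })
  })
  structure(list(schedule = schedule, config = config, state = state,
                 drive = drive, subjects = subjects),
            class = "synthetic_cohort")
}
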