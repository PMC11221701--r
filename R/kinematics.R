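# Reach-trajectory preprocessing: filtering, movement onset and RT, hand
# deviation at peak velocity, exclusions, baseline correction, cycle and
# phase summaries.

#' Wrap an angle to (-180, 180] degrees
#'
#' @param a Angle(s) in degrees.
#' @return Wrapped angle(s).
#' @export
wrap_deg <- function(a) {
  w <- a %% 360
  w[w > 180] <- w[w > 180] - 360
  w
}

#' Zero-phase low-pass filter a hand trajectory
#'
#' Butterworth filter applied forward and backward (zero phase lag) to the
#' x and y position samples; time stamps are unchanged.
#'
#' @param traj Data frame with columns `t_s` (uniformly sampled, strictly
#'   increasing), `x_cm`, `y_cm`.
#' @param cutoff_hz Cutoff frequency in Hz.
#' @param order Filter order (of the one-pass filter; applied twice).
#' @return The trajectory with filtered positions.
#' @export
lowpass_filter <- function(traj, cutoff_hz = 10, order = 4) {
  stopifnot(all(c("t_s", "x_cm", "y_cm") %in% names(traj)))
  if (nrow(traj) < 8) stop("need at least 8 samples", call. = FALSE)
  dt <- diff(traj$t_s)
  if (any(dt <= 0)) stop("time must be strictly increasing", call. = FALSE)
  fs <- 1 / stats::median(dt)
  if (cutoff_hz >= fs / 2)
    stop("cutoff must be below the Nyquist frequency ", fs / 2, " Hz",
         call. = FALSE)
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  traj$x_cm <- .filtfilt_padded(bf, traj$x_cm)
  traj$y_cm <- .filtfilt_padded(bf, traj$y_cm)
  traj
}

# Zero-phase filtering with odd-symmetric edge reflection to suppress the
# startup/end transients of the forward-backward pass.
.filtfilt_padded <- function(bf, x) {
  n <- length(x)
  np <- min(n - 1L, 3L * (max(length(bf$b), length(bf$a)) - 1L) * 3L)
  pre <- 2 * x[1] - x[(np + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - np)]
  y <- as.numeric(signal::filtfilt(bf, c(pre, x, post)))
  y[(np + 1L):(np + n)]
}

# Euclidean hand speed (cm/s) by central differences; one-sided endpoints.
.trial_speed <- function(traj) {
  n <- nrow(traj)
  t <- traj$t_s
  grad <- function(p) {
    g <- numeric(n)
    g[1] <- (p[2] - p[1]) / (t[2] - t[1])
    g[n] <- (p[n] - p[n - 1]) / (t[n] - t[n - 1])
    if (n > 2) {
      i <- 2:(n - 1)
      g[i] <- (p[i + 1] - p[i - 1]) / (t[i + 1] - t[i - 1])
    }
    g
  }
  sqrt(grad(traj$x_cm)^2 + grad(traj$y_cm)^2)
}

#' Movement onset, reaction time and peak speed of a trial
#'
#' Movement onset is the first sample at which hand speed crosses 5% of the
#' trial's peak speed; RT is the time from the go cue to onset. Speed is
#' obtained by differentiating the (filtered) positions. Trials whose peak
#' speed stays below `no_move_floor` are flagged as no-movement.
#'
#' @param traj Filtered trajectory data frame (`t_s`, `x_cm`, `y_cm`).
#' @param go_cue_s Go-cue time in seconds.
#' @param onset_frac Fraction of peak speed defining onset.
#' @param no_move_floor Peak-speed floor in cm/s below which the trial is
#'   marked `no_movement`.
#' @return A list: `onset_idx`, `onset_s`, `rt_ms`, `peak_speed`,
#'   `no_movement`, and the `speed` vector.
#' @export
movement_onset_rt <- function(traj, go_cue_s = 0, onset_frac = 0.05,
                              no_move_floor = 2) {
  speed <- .trial_speed(traj)
  peak <- max(speed)
  if (!is.finite(peak) || peak < no_move_floor)
    return(list(onset_idx = NA_integer_, onset_s = NA_real_,
                rt_ms = NA_real_, peak_speed = peak, no_movement = TRUE,
                speed = speed))
  onset_idx <- which(speed >= onset_frac * peak)[1]
  onset_s <- traj$t_s[onset_idx]
  list(onset_idx = onset_idx, onset_s = onset_s,
       rt_ms = (onset_s - go_cue_s) * 1000, peak_speed = peak,
       no_movement = FALSE, speed = speed)
}

#' Hand deviation at peak movement velocity
#'
#' Signed angle (counterclockwise positive, wrapped to (-180, 180]) between
#' the start-to-original-target line and the start-to-hand line at the
#' moment of peak speed. The peak-speed search is restricted to the window
#' from movement onset to the first crossing of the reach distance (where
#' the cursor froze), falling back to the whole trial if that distance is
#' never reached.
#'
#' @param traj Filtered trajectory data frame, positions relative to the
#'   start-circle centre.
#' @param target_dir_deg Original target direction in degrees.
#' @param onset Result of [movement_onset_rt()] for this trial (computed if
#'   omitted).
#' @param reach_distance Reach distance in cm.
#' @return Deviation in degrees, or `NA` if the hand is at the start
#'   position at peak speed.
#' @export
hand_deviation_at_peak <- function(traj, target_dir_deg, onset = NULL,
                                   reach_distance = 10) {
  if (is.null(onset)) onset <- movement_onset_rt(traj)
  if (isTRUE(onset$no_movement)) return(NA_real_)
  r <- sqrt(traj$x_cm^2 + traj$y_cm^2)
  end_idx <- which(r >= reach_distance)[1]
  if (is.na(end_idx)) end_idx <- nrow(traj)
  win <- onset$onset_idx:end_idx
  peak_idx <- win[which.max(onset$speed[win])]
  px <- traj$x_cm[peak_idx]; py <- traj$y_cm[peak_idx]
  if (px == 0 && py == 0) return(NA_real_)
  wrap_deg(atan2(py, px) * 180 / pi - target_dir_deg)
}

#' Compute trial-level metrics for one raw trial
#'
#' Filters the trajectory, finds movement onset and RT, and measures the
#' hand deviation at peak velocity.
#'
#' @param traj Raw trajectory data frame (`t_s`, `x_cm`, `y_cm`).
#' @param target_dir_deg Original target direction in degrees.
#' @param go_cue_s Go-cue time in seconds.
#' @param stylus_lift Whether the stylus was lifted mid-trial (data loss).
#' @param cutoff_hz Low-pass cutoff in Hz.
#' @param reach_distance Reach distance in cm.
#' @return One-row data frame: hand_dev_deg, rt_ms, peak_speed, excluded,
#'   reason. Exclusion here covers `no_movement` and `stylus_lift`; the
#'   deviation-magnitude rule is applied by [apply_exclusions()].
#' @export
process_trial <- function(traj, target_dir_deg, go_cue_s = 0,
                          stylus_lift = FALSE, cutoff_hz = 10,
                          reach_distance = 10) {
  if (isTRUE(stylus_lift))
    return(data.frame(hand_dev_deg = NA_real_, rt_ms = NA_real_,
                      peak_speed = NA_real_, excluded = TRUE,
                      reason = "stylus_lift"))
  traj <- lowpass_filter(traj, cutoff_hz)
  onset <- movement_onset_rt(traj, go_cue_s)
  if (onset$no_movement)
    return(data.frame(hand_dev_deg = NA_real_, rt_ms = NA_real_,
                      peak_speed = onset$peak_speed, excluded = TRUE,
                      reason = "no_movement"))
  dev <- hand_deviation_at_peak(traj, target_dir_deg, onset, reach_distance)
  data.frame(hand_dev_deg = dev, rt_ms = onset$rt_ms,
             peak_speed = onset$peak_speed,
             excluded = is.na(dev),
             reason = if (is.na(dev)) "no_movement" else "none")
}

#' Apply the deviation-magnitude exclusion rule
#'
#' Flags trials whose absolute hand deviation exceeds `max_dev` degrees
#' (strictly greater; a deviation of exactly `max_dev` is retained), on top
#' of any no-movement / stylus-lift exclusions already present.
#'
#' @param trials Trial table with columns `hand_dev_deg`, `excluded`,
#'   `reason`.
#' @param max_dev Exclusion threshold in degrees.
#' @return The trial table with updated flags; the overall exclusion
#'   fraction is attached as attribute `"exclusion_fraction"`.
#' @export
apply_exclusions <- function(trials, max_dev = 85) {
  big <- !trials$excluded & !is.na(trials$hand_dev_deg) &
    abs(trials$hand_dev_deg) > max_dev
  trials$excluded[big] <- TRUE
  trials$reason[big] <- "deviation_gt_85"
  attr(trials, "exclusion_fraction") <- mean(trials$excluded)
  trials
}

#' Subtract per-subject baseline directional bias
#'
#' The bias is the mean hand deviation over all valid baseline trials (both
#' baseline sub-blocks) of each subject, and is subtracted from every trial
#' of that subject.
#'
#' @param trials Trial table with columns `subject`, `block`,
#'   `hand_dev_deg`, `excluded`.
#' @return The table with an added `hand_dev_bc_deg` column.
#' @export
baseline_correct <- function(trials) {
  trials$hand_dev_bc_deg <- NA_real_
  for (s in unique(trials$subject)) {
    i <- trials$subject == s
    base <- i & grepl("^baseline", trials$block) & !trials$excluded
    if (!any(base))
      stop("subject ", s, " has no valid baseline trials", call. = FALSE)
    bias <- mean(trials$hand_dev_deg[base])
    trials$hand_dev_bc_deg[i] <- trials$hand_dev_deg[i] - bias
  }
  trials
}

#' Average a per-trial series into 10-trial cycles
#'
#' @param trials Trial table with `subject`, `cycle`, `hand_dev_bc_deg`,
#'   `rt_ms`, `excluded`.
#' @param value Column to average (baseline-corrected deviation by
#'   default).
#' @return Data frame: subject, cycle, mean_dev (NA when a cycle has no
#'   valid trial), mean_rt, n_valid.
#' @export
cycle_average <- function(trials, value = "hand_dev_bc_deg") {
  out <- do.call(rbind, lapply(split(trials, trials[c("cycle", "subject")]),
    function(d) {
      ok <- !d$excluded
      data.frame(subject = d$subject[1], cycle = d$cycle[1],
                 mean_dev = if (any(ok)) mean(d[[value]][ok]) else NA_real_,
                 mean_rt = if (any(ok)) mean(d$rt_ms[ok]) else NA_real_,
                 n_valid = sum(ok))
    }))
  out <- out[order(out$subject, out$cycle), ]
  rownames(out) <- NULL
  out
}

#' Subjects-by-cycles matrix of cycle means
#'
#' @param cycles Output of [cycle_average()].
#' @return Numeric matrix, one row per subject, one column per cycle.
#' @export
cycle_matrix <- function(cycles) {
  subjects <- unique(cycles$subject)
  n_cyc <- max(cycles$cycle)
  m <- matrix(NA_real_, nrow = length(subjects), ncol = n_cyc,
              dimnames = list(subjects, NULL))
  for (i in seq_along(subjects)) {
    d <- cycles[cycles$subject == subjects[i], ]
    m[i, d$cycle] <- d$mean_dev
  }
  m
}

.window_mean <- function(x, idx, head = TRUE, k = 10L) {
  if (!length(idx)) return(NA_real_)
  w <- if (head) utils::head(idx, k) else utils::tail(idx, k)
  mean(x[w], na.rm = TRUE)
}

#' Phase summaries of one subject's corrected trial series
#'
#' Early learning = mean baseline-corrected deviation over the first 10
#' learning trials; late learning = last 10 learning trials; early
#' no-feedback (and feedback) washout = first 10 trials of the respective
#' washout sub-block; late washout = last 10 washout trials. The early RT
#' change is the mean RT of the first 10 learning trials minus the mean RT
#' of the last 10 baseline trials.
#'
#' @param trials One subject's trial table with `block`, `hand_dev_bc_deg`,
#'   `rt_ms`, `excluded` columns.
#' @return A list of phase means (degrees; RT change in ms).
#' @export
phase_metrics <- function(trials) {
  stopifnot(length(unique(trials$subject)) == 1L)
  if (!any(trials$block == "learning"))
    stop("trial table has no learning block", call. = FALSE)
  dev <- ifelse(trials$excluded, NA, trials$hand_dev_bc_deg)
  rt <- ifelse(trials$excluded, NA, trials$rt_ms)
  idx <- function(b) which(trials$block %in% b)
  learn <- idx("learning")
  washout <- idx(c("washout_nofb", "washout_fb"))
  list(
    early_learning = .window_mean(dev, learn),
    late_learning = .window_mean(dev, learn, head = FALSE),
    early_nofb_washout = .window_mean(dev, idx("washout_nofb")),
    early_fb_washout = .window_mean(dev, idx("washout_fb")),
    late_washout = .window_mean(dev, washout, head = FALSE),
    rt_change_early =
      .window_mean(rt, learn) -
      .window_mean(rt, idx(c("baseline_nofb", "baseline_fb")),
                   head = FALSE)
  )
}

#' Run the full kinematic pipeline on a synthetic cohort
#'
#' Filters every raw trial, computes trial metrics, applies exclusions,
#' baseline-corrects, and returns the tidy trial table.
#'
#' @param cohort A cohort from [generate_raw_trials()].
#' @param cutoff_hz Low-pass cutoff in Hz.
#' @param max_dev Deviation exclusion threshold in degrees.
#' @return Trial table with columns subject, experiment, group, trial,
#'   cycle, block, hand_dev_deg, hand_dev_bc_deg, rt_ms, excluded, reason;
#'   exclusion fraction attached as an attribute.
#' @export
preprocess_cohort <- function(cohort, cutoff_hz = 10, max_dev = 85) {
  schedule <- cohort$schedule
  layout <- attr(schedule, "layout")
  rows <- lapply(seq_along(cohort$subjects), function(s) {
    subj <- cohort$subjects[[s]]
    m <- do.call(rbind, lapply(seq_len(nrow(schedule)), function(i) {
      process_trial(subj$trajectories[[i]], schedule$target_dir_deg[i],
                    go_cue_s = 0, cutoff_hz = cutoff_hz,
                    reach_distance = layout$reach_distance)
    }))
    cbind(data.frame(subject = s,
                     experiment = attr(schedule, "experiment"),
                     group = attr(schedule, "group"),
                     trial = schedule$trial, cycle = schedule$cycle,
                     block = schedule$block), m)
  })
  trials <- do.call(rbind, rows)
  trials <- apply_exclusions(trials, max_dev)
  frac <- attr(trials, "exclusion_fraction")
  trials <- baseline_correct(trials)
  trials <- trials[, c("subject", "experiment", "group", "trial", "cycle",
                       "block", "hand_dev_deg", "hand_dev_bc_deg", "rt_ms",
                       "excluded", "reason")]
  attr(trials, "exclusion_fraction") <- frac
  trials
}
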