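# Experiment designs: block structure, target geometry, perturbation logic.

#' Target layout of the reaching task
#'
#' Four targets arranged radially in 90-degree increments at a fixed reach
#' distance, together with start- and target-circle sizes.
#'
#' @param directions Target directions in degrees (counterclockwise from the
#'   positive x-axis).
#' @param reach_distance Start-to-target distance in cm.
#' @param start_diameter Start circle diameter in cm.
#' @param target_diameter Target diameter in cm.
#' @return A list of class `"target_layout"`.
#' @export
target_layout <- function(directions = c(0, 90, 180, 270),
                          reach_distance = 10,
                          start_diameter = 0.9,
                          target_diameter = 0.98) {
  if (length(directions) != 4L || anyDuplicated(directions))
    stop("directions must be 4 distinct angles", call. = FALSE)
  d <- sort(directions %% 360)
  if (any(diff(d) != 90))
    stop("directions must be 90 degrees apart", call. = FALSE)
  if (reach_distance <= 0 || start_diameter <= 0 || target_diameter <= 0)
    stop("reach_distance and diameters must be positive", call. = FALSE)
  structure(list(directions = directions,
                 reach_distance = reach_distance,
                 start_diameter = start_diameter,
                 target_diameter = target_diameter),
            class = "target_layout")
}

# The fixed pseudo-random target order was shared by all participants; this
# seed realizes that fixed order and is recorded on every built schedule.
.default_target_seed <- 20240703L

# Per-design configuration. Jumps are stored sign-normalized (positive =
# direction of required compensation); `sign_flip` records whether raw data
# for the group must be negated on load (clockwise perturbations).
.design_table <- function() {
  blocks_e1 <- list(baseline_nofb = 20L, baseline_fb = 20L, learning = 240L,
                    washout_nofb = 20L, washout_fb = 20L)
  blocks_e3 <- list(baseline_fb = 40L, learning = 200L,
                    washout_nofb = 40L, washout_fb = 120L)
  # E4 jump-10 group runs its feedback washout sub-block before the
  # no-feedback one, unlike E1/E2.
  blocks_e4a <- list(baseline_nofb = 20L, baseline_fb = 20L, learning = 240L,
                     washout_fb = 20L, washout_nofb = 20L)
  list(
    "E1.Hit" = list(blocks = blocks_e1, jump_deg = 10, feedback = "clamped",
                    clamp_offset_deg = 0, start_diameter = 0.9,
                    target_diameter = 0.98, jumped_target_diameter = 4.6,
                    n_subjects = 15L, spe_present = TRUE, sign_flip = FALSE),
    "E1.Miss" = list(blocks = blocks_e1, jump_deg = 10, feedback = "clamped",
                     clamp_offset_deg = 0, start_diameter = 0.9,
                     target_diameter = 0.98, jumped_target_diameter = 0.98,
                     n_subjects = 15L, spe_present = TRUE, sign_flip = FALSE),
    "E2.J10" = list(blocks = blocks_e1, jump_deg = 10, feedback = "clamped",
                    clamp_offset_deg = 0, start_diameter = 0.9,
                    target_diameter = 0.98, jumped_target_diameter = 0.98,
                    n_subjects = 15L, spe_present = FALSE, sign_flip = TRUE),
    "E2.J20" = list(blocks = blocks_e1, jump_deg = 20, feedback = "clamped",
                    clamp_offset_deg = 0, start_diameter = 0.9,
                    target_diameter = 0.98, jumped_target_diameter = 0.98,
                    n_subjects = 15L, spe_present = FALSE, sign_flip = TRUE),
    "E3.Clamp" = list(blocks = blocks_e3, jump_deg = 0, feedback = "clamped",
                      clamp_offset_deg = 30, start_diameter = 1.2,
                      target_diameter = 1.5, jumped_target_diameter = 1.5,
                      n_subjects = 15L, spe_present = TRUE, sign_flip = FALSE),
    "E3.ClampJump" = list(blocks = blocks_e3, jump_deg = 30,
                          feedback = "clamped", clamp_offset_deg = 30,
                          start_diameter = 1.2, target_diameter = 1.5,
                          jumped_target_diameter = 1.5, n_subjects = 15L,
                          spe_present = TRUE, sign_flip = FALSE),
    "E4.J10CCW" = list(blocks = blocks_e4a, jump_deg = 10,
                       feedback = "veridical", clamp_offset_deg = 0,
                       start_diameter = 0.9, target_diameter = 0.98,
                       jumped_target_diameter = 0.98, n_subjects = 10L,
                       spe_present = FALSE, sign_flip = FALSE),
    "E4.J30CW" = list(blocks = blocks_e3, jump_deg = 30,
                      feedback = "veridical", clamp_offset_deg = 0,
                      start_diameter = 1.2, target_diameter = 1.5,
                      jumped_target_diameter = 1.5, n_subjects = 15L,
                      spe_present = FALSE, sign_flip = TRUE)
  )
}

#' Available experiment/group designs
#'
#' @return A data frame with one row per design (experiment, group).
#' @export
list_designs <- function() {
  keys <- names(.design_table())
  parts <- strsplit(keys, ".", fixed = TRUE)
  data.frame(experiment = vapply(parts, `[`, "", 1L),
             group = vapply(parts, `[`, "", 2L))
}

#' Pseudo-random target direction sequence
#'
#' Orders the four target directions so that each appears exactly once in
#' every consecutive non-overlapping window of four trials, matching the
#' constraint used in the experiments. The order is deterministic given the
#' seed; the same fixed order is used for all subjects of a schedule.
#'
#' @param n_trials Number of trials; must be divisible by 4.
#' @param seed Integer seed controlling the permutations.
#' @param directions The four directions in degrees.
#' @return Numeric vector of target directions, one per trial.
#' @export
target_direction_sequence <- function(n_trials, seed = .default_target_seed,
                                      directions = c(0, 90, 180, 270)) {
  if (n_trials %% 4 != 0)
    stop("n_trials must be divisible by 4", call. = FALSE)
  withr::with_seed(seed, {
    unlist(lapply(seq_len(n_trials / 4), function(i) sample(directions)))
  })
}

#' Hit/miss outcome of a clamped cursor against a (possibly jumped) target
#'
#' The cursor travels `reach_distance` along `clamp_offset_deg` (relative to
#' the original target direction) and freezes; the target centre sits at
#' `reach_distance` along `jump_deg`. The cursor hits when the chord distance
#' `2 R sin(|jump - clamp| / 2)` does not exceed the target radius (plus an
#' optional cursor radius; by default the cursor is a point).
#'
#' @param jump_deg Signed target jump in degrees (0 = stationary target).
#' @param clamp_offset_deg Signed clamp direction in degrees relative to the
#'   original target.
#' @param target_diameter Diameter in cm of the target the cursor is judged
#'   against (the jumped target on jump trials).
#' @param reach_distance Reach distance in cm.
#' @param cursor_radius Optional cursor radius in cm added to the target
#'   radius.
#' @return `"hit"` or `"miss"`.
#' @export
cursor_outcome <- function(jump_deg, clamp_offset_deg, target_diameter,
                           reach_distance = 10, cursor_radius = 0) {
  if (target_diameter <= 0 || reach_distance <= 0)
    stop("target_diameter and reach_distance must be positive", call. = FALSE)
  sep <- abs(jump_deg - clamp_offset_deg)
  chord <- 2 * reach_distance * sin(sep * pi / 360)
  if (chord <= target_diameter / 2 + cursor_radius) "hit" else "miss"
}

#' Build a trial schedule for one experimental group
#'
#' Encodes the block structure, target geometry, jump and clamp logic of the
#' eight designs: Experiment 1 (Hit / Miss: 10 deg jump under an error clamp,
#' with or without enlarged jumped target), Experiment 2 (J10 / J20: jumps to
#' be ignored under a clamp), Experiment 3 (Clamp / ClampJump: 30 deg rotated
#' clamp with stationary or co-jumped target) and Experiment 4 (J10CCW /
#' J30CW: jumps with veridical feedback). Jump angles are sign-normalized so
#' compensation is positive.
#'
#' @param experiment One of `"E1"`, `"E2"`, `"E3"`, `"E4"`.
#' @param group Group label within the experiment (see [list_designs()]).
#' @param target_seed Seed for the fixed pseudo-random target order.
#' @return A data frame of class `"reach_schedule"` with one row per trial
#'   and columns trial, cycle, block, target_dir_deg, jump_deg,
#'   clamp_offset_deg, target_diameter_cm, feedback. Design metadata
#'   (experiment, group, layout, nominal n, SPE presence, sign flip) is
#'   attached as attributes.
#' @export
build_schedule <- function(experiment, group,
                           target_seed = .default_target_seed) {
  key <- paste(experiment, group, sep = ".")
  tab <- .design_table()
  if (!key %in% names(tab))
    stop("unknown design: ", key, "; see list_designs()", call. = FALSE)
  d <- tab[[key]]

  block_names <- names(d$blocks)
  counts <- unlist(d$blocks)
  n_trials <- sum(counts)
  block <- rep(block_names, counts)
  is_learning <- block == "learning"

  sched <- data.frame(
    trial = seq_len(n_trials),
    cycle = rep(seq_len(n_trials / 10), each = 10L),
    block = block,
    target_dir_deg = target_direction_sequence(n_trials, target_seed),
    jump_deg = ifelse(is_learning, d$jump_deg, 0),
    clamp_offset_deg = ifelse(is_learning & d$feedback == "clamped",
                              d$clamp_offset_deg, 0),
    target_diameter_cm = ifelse(is_learning, d$jumped_target_diameter,
                                d$target_diameter),
    feedback = ifelse(is_learning, d$feedback,
                      ifelse(grepl("nofb", block), "none", "veridical")),
    stringsAsFactors = FALSE
  )
  structure(sched,
            class = c("reach_schedule", "data.frame"),
            experiment = experiment, group = group,
            layout = target_layout(start_diameter = d$start_diameter,
                                   target_diameter = d$target_diameter),
            n_subjects_nominal = d$n_subjects,
            spe_present = d$spe_present,
            sign_flip = d$sign_flip,
            target_seed = target_seed)
}

#' @export
print.reach_schedule <- function(x, ...) {
  cat(sprintf("<reach_schedule> %s/%s: %d trials, %d cycles\n",
              attr(x, "experiment"), attr(x, "group"),
              nrow(x), nrow(x) / 10L))
  tab <- table(factor(x$block, levels = unique(x$block)))
  for (b in names(tab)) cat(sprintf("  %-14s %4d trials\n", b, tab[[b]]))
  invisible(x)
}

#' Per-cycle error-drive indicators for model fitting
#'
#' Converts a schedule into the cycle-resolution drive a state-space learner
#' sees: whether a sensory prediction error (SPE) is present, whether a task
#' performance error (TPE) is present, and whether the cycle enters the fit.
#' SPE presence is a property of the design (error-clamp experiments E1 and
#' E3 induce it; E2 and E4 do not); TPE presence on learning cycles follows
#' the geometric hit/miss outcome of the clamped cursor against the (jumped)
#' target. Feedback-washout cycles are masked out of fits because the error
#' is no longer constant there; no-feedback washout cycles carry no drive.
#'
#' @param schedule A `"reach_schedule"` from [build_schedule()].
#' @return A data frame with one row per cycle: cycle, block, spe_on,
#'   tpe_on, fit_mask (all indicators 0/1).
#' @export
drive_sequence <- function(schedule) {
  stopifnot(inherits(schedule, "reach_schedule"))
  first <- schedule[!duplicated(schedule$cycle), ]
  learning <- first$block == "learning"
  spe_on <- as.integer(learning & attr(schedule, "spe_present"))
  layout <- attr(schedule, "layout")
  miss <- vapply(which(learning), function(i) {
    cursor_outcome(first$jump_deg[i], first$clamp_offset_deg[i],
                   first$target_diameter_cm[i],
                   layout$reach_distance) == "miss"
  }, logical(1))
  tpe_on <- integer(nrow(first))
  tpe_on[learning] <- as.integer(miss)
  data.frame(cycle = first$cycle,
             block = first$block,
             spe_on = spe_on,
             tpe_on = tpe_on,
             fit_mask = as.integer(first$block != "washout_fb"))
}

#' Write a schedule as a tidy per-trial CSV
#'
#' @param schedule A `"reach_schedule"`.
#' @param path Output file path.
#' @param subject Subject identifier recorded in every row.
#' @return The path, invisibly.
#' @export
write_schedule_csv <- function(schedule, path, subject = 1L) {
  stopifnot(inherits(schedule, "reach_schedule"))
  out <- data.frame(subject = subject,
                    experiment = attr(schedule, "experiment"),
                    group = attr(schedule, "group"),
                    trial = schedule$trial,
                    cycle = schedule$cycle,
                    block = schedule$block,
                    target_dir_deg = schedule$target_dir_deg,
                    jump_deg = schedule$jump_deg,
                    clamp_offset_deg = schedule$clamp_offset_deg,
                    target_diameter_cm = schedule$target_diameter_cm,
                    feedback = schedule$feedback)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
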