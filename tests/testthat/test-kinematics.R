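make_traj <- function(t, x, y) data.frame(t_s = t, x_cm = x, y_cm = y)

test_that("zero-phase filter passes DC and the band, blocks above cutoff", {
  t <- seq(0, 2, by = 0.01)
  flat <- lowpass_filter(make_traj(t, rep(3, length(t)), rep(-1, length(t))))
  expect_equal(flat$x_cm, rep(3, length(t)), tolerance = 1e-4)
  expect_equal(flat$y_cm, rep(-1, length(t)), tolerance = 1e-4)

  mid <- 51:150  # away from the edges
  slow <- lowpass_filter(make_traj(t, sin(2 * pi * 1 * t), 0 * t))
  expect_gt(max(abs(slow$x_cm[mid])), 0.99)
  fast <- lowpass_filter(make_traj(t, sin(2 * pi * 40 * t), 0 * t))
  expect_lt(max(abs(fast$x_cm[mid])), 0.01)

  expect_error(lowpass_filter(make_traj(t, t, t), cutoff_hz = 60),
               "Nyquist")
  expect_error(lowpass_filter(make_traj(t[1:4], 1:4, 1:4)), "8 samples")
})

test_that("movement onset is the first 5%-of-peak speed crossing", {
  # stationary until 0.30 s, then a 20 cm/s ramp; central differences put
  # half the ramp speed (10 cm/s, above the 1 cm/s threshold) on the last
  # stationary sample at t = 0.30 s, which is therefore the onset
  t <- seq(0, 1, by = 0.01)
  x <- pmax(t - 0.3, 0) * 20
  on <- movement_onset_rt(make_traj(t, x, 0 * t), go_cue_s = 0)
  expect_equal(on$peak_speed, 20, tolerance = 0.01)
  expect_equal(on$rt_ms, 300)
  # rt measured from a later go cue; zero when the cue sits at onset
  expect_equal(movement_onset_rt(make_traj(t, x, 0 * t),
                                 go_cue_s = 0.30)$rt_ms, 0)
  # no movement at all
  still <- movement_onset_rt(make_traj(t, 0 * t, 0 * t))
  expect_true(still$no_movement)
  expect_true(is.na(still$rt_ms))
})

test_that("hand deviation at peak velocity follows the sign convention", {
  t <- seq(0, 1, by = 0.01)
  straight <- function(ang) {
    r <- pmin(pmax(t - 0.2, 0) * 20, 12)
    make_traj(t, r * cos(ang * pi / 180), r * sin(ang * pi / 180))
  }
  expect_equal(hand_deviation_at_peak(straight(100), 90), 10,
               tolerance = 1e-6)
  expect_equal(hand_deviation_at_peak(straight(90), 90), 0,
               tolerance = 1e-6)
  expect_equal(hand_deviation_at_peak(straight(80), 90), -10,
               tolerance = 1e-6)
  # wrap: a 271 deg path against a 0 deg target is -89, not 271
  expect_equal(hand_deviation_at_peak(straight(271), 0), -89,
               tolerance = 1e-6)
})

test_that("deviation-magnitude exclusion is strict at 85 degrees", {
  tr <- data.frame(hand_dev_deg = c(90, 85, -86, 10, NA),
                   excluded = c(FALSE, FALSE, FALSE, FALSE, TRUE),
                   reason = c("none", "none", "none", "none",
                              "no_movement"))
  out <- apply_exclusions(tr)
  expect_identical(out$excluded, c(TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_identical(out$reason[c(1, 3)], rep("deviation_gt_85", 2))
  expect_equal(attr(out, "exclusion_fraction"), 3 / 5)
})

test_that("baseline correction subtracts the per-subject bias", {
  tr <- data.frame(subject = rep(1:2, each = 40),
                   block = rep(rep(c("baseline_fb", "learning"),
                                   each = 20), 2),
                   hand_dev_deg = c(rep(2, 20), rep(12, 20),
                                    rep(0, 20), rep(10, 20)),
                   excluded = FALSE)
  out <- baseline_correct(tr)
  expect_equal(out$hand_dev_bc_deg[1:20], rep(0, 20))
  expect_equal(out$hand_dev_bc_deg[21:40], rep(10, 20))  # plateau 12 - 2
  expect_equal(out$hand_dev_bc_deg[41:80], tr$hand_dev_deg[41:80])
  # correcting again changes nothing once the bias is gone
  tr2 <- out
  tr2$hand_dev_deg <- tr2$hand_dev_bc_deg
  expect_equal(baseline_correct(tr2)$hand_dev_bc_deg,
               out$hand_dev_bc_deg)
  tr$excluded <- TRUE
  expect_error(baseline_correct(tr), "no valid baseline")
})

test_that("cycle averages use valid trials and propagate empty cycles", {
  tr <- data.frame(subject = 1, cycle = rep(1:3, each = 10),
                   hand_dev_bc_deg = rep(c(5, 1, 2), each = 10),
                   rt_ms = 300, excluded = FALSE)
  tr$hand_dev_bc_deg[11] <- 100   # excluded outlier in cycle 2
  tr$excluded[11] <- TRUE
  tr$excluded[21:30] <- TRUE      # cycle 3 entirely invalid
  out <- cycle_average(tr)
  expect_equal(out$mean_dev, c(5, 1, NA))
  expect_equal(out$n_valid, c(10, 9, 0))
  m <- cycle_matrix(out)
  expect_equal(dim(m), c(1, 3))
  expect_equal(m[1, ], c(5, 1, NA))
})

test_that("phase metrics average exactly the defining 10-trial windows", {
  s <- build_schedule("E1", "Hit")
  tr <- data.frame(subject = 1, block = s$block, trial = s$trial,
                   hand_dev_bc_deg = s$trial / 10, rt_ms = 300,
                   excluded = FALSE)
  pm <- phase_metrics(tr)
  learn <- which(s$block == "learning")
  expect_equal(pm$early_learning, mean(head(learn, 10) / 10))
  expect_equal(pm$late_learning, mean(tail(learn, 10) / 10))
  expect_equal(pm$early_nofb_washout,
               mean(head(which(s$block == "washout_nofb"), 10) / 10))
  expect_equal(pm$rt_change_early, 0)   # constant RT across blocks
  flat <- tr; flat$hand_dev_bc_deg <- 0
  expect_true(all(unlist(phase_metrics(flat)[1:5]) == 0))
})

test_that("noise-free cohorts pass through the pipeline with full fidelity", {
  s <- build_schedule("E1", "Miss")
  cfg <- generator_config(generating_model = "strategy_plus_spe",
                          aim_policy = "aim_jumped",
                          angular_noise_sd = 0, rt_jitter_sdlog = 0,
                          n_subjects = 1, seed = 7)
  cohort <- generate_raw_trials(s, cfg)
  trials <- preprocess_cohort(cohort)
  truth <- cohort$subjects[[1]]$truth
  # programmed aim recovered to well under 0.1 degree, nothing excluded
  expect_lt(max(abs(trials$hand_dev_deg -
                      wrap_deg(truth$aim_deg - s$target_dir_deg))), 0.1)
  expect_equal(attr(trials, "exclusion_fraction"), 0)
  # RT recovered within one sample period (10 ms at 100 Hz)
  expect_lte(max(abs(trials$rt_ms - truth$rt_ms)), 10)
})
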