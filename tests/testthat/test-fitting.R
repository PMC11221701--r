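test_that("noiseless parameter recovery is exact for all three protocols", {
  set.seed(5)
  e1_hit <- drive_sequence(build_schedule("E1", "Hit"))
  e1_miss <- drive_sequence(build_schedule("E1", "Miss"))
  cfg <- fit_config(n_starts = 8, seed = 2)
  for (i in 1:12) {
    p <- draw_params()
    obs <- simulate_spe(p["A"], p["B"], e1_hit)
    f <- fit_spe_only(obs, e1_hit, cfg)
    expect_equal(unname(f$params), unname(p), tolerance = 1e-3)

    q <- draw_params()
    obs2 <- simulate_independent(p["A"], p["B"], q["A"], q["B"],
                                 e1_miss)$x_net
    f2 <- fit_independent_stage2(obs2, e1_miss,
                                 c(A_spe = unname(p["A"]),
                                   B_spe_drive = unname(p["B"])), cfg)
    expect_equal(unname(f2$params), unname(q), tolerance = 1e-3)

    g <- c(runif(1, 0.5, 1.5), runif(1, 0.1, 2))
    obs3 <- simulate_interaction(p["A"], p["B"], g[1], g[2], e1_hit)
    f3 <- fit_interaction(obs3, e1_hit, cfg,
                          frozen = c(A_spe = unname(p["A"]),
                                     B_spe_drive = unname(p["B"])),
                          estimate_gains = TRUE)
    expect_equal(unname(f3$params), g, tolerance = 1e-3)
  }
})

test_that("flat observations yield zero drive and zero objective", {
  d <- drive_sequence(build_schedule("E1", "Hit"))
  f <- suppressWarnings(   # flat series has no variance for R^2
    fit_spe_only(rep(0, nrow(d)), d, fit_config(n_starts = 5)))
  expect_equal(unname(f$params["B_spe_drive"]), 0, tolerance = 1e-5)
  expect_equal(f$objective, 0, tolerance = 1e-8)

  # observation equal to the frozen SPE prediction leaves nothing for TPE
  dm <- drive_sequence(build_schedule("E1", "Miss"))
  frozen <- c(A_spe = 0.8, B_spe_drive = 1)
  obs <- simulate_spe(0.8, 1, dm)
  f2 <- fit_independent_stage2(obs, dm, frozen, fit_config(n_starts = 5))
  expect_equal(unname(f2$params["B_tpe_drive"]), 0, tolerance = 1e-5)

  # flat-zero series drives the gain on the drive to zero
  f3 <- suppressWarnings(
    fit_interaction(rep(0, nrow(d)), d, fit_config(n_starts = 5),
                    frozen = frozen, estimate_gains = TRUE))
  expect_equal(unname(f3$params["G_B"]), 0, tolerance = 1e-5)
})

test_that("multi-start optimum matches the exhaustive grid oracle", {
  set.seed(23)
  cfg <- fit_config(n_starts = 10, seed = 3)
  for (i in 1:8) {
    n <- sample(5:8, 1)
    drive <- make_drive(rbinom(n, 1, 0.7))
    p <- draw_params()
    obs <- simulate_spe(p["A"], p["B"], drive) + rnorm(n, 0, 0.5)
    fit <- fit_spe_only(obs, drive, cfg)
    grid <- grid_search_spe(obs, drive, cfg$drive_bound_deg)
    # the continuous optimum can only improve on the grid, and the grid
    # must come within one grid step of it
    expect_lte(fit$objective, grid$sse + 1e-8)
    expect_lte(grid$sse - fit$objective, grid$step_slack + 1e-8)
  }
})

test_that("objective does not increase when frozen parameters are released", {
  set.seed(31)
  dh <- drive_sequence(build_schedule("E1", "Hit"))
  dm <- drive_sequence(build_schedule("E1", "Miss"))
  cfg <- fit_config(n_starts = 10)
  frozen <- c(A_spe = 0.7, B_spe_drive = 1.2)
  for (i in 1:5) {
    # gains released from their pinned value of 1 can only fit better
    obs <- simulate_interaction(0.8, 1, 0.9, 1.3, dh) + rnorm(nrow(dh))
    pinned_sse <- sum((obs - simulate_interaction(
      frozen["A_spe"], frozen["B_spe_drive"], 1, 1, dh))[
        drive_sequence(build_schedule("E1", "Hit"))$fit_mask == 1]^2)
    released <- fit_interaction(obs, dh, cfg, frozen = frozen,
                                estimate_gains = TRUE)
    expect_lte(released$objective, pinned_sse + 1e-8)

    # a TPE process released from zero drive can only fit better
    obs2 <- simulate_independent(0.8, 1, 0.7, 3, dm)$x_net +
      rnorm(nrow(dm))
    fr2 <- c(A_spe = 0.8, B_spe_drive = 1)
    zero_tpe_sse <- sum((obs2 - simulate_spe(0.8, 1, dm))[
      dm$fit_mask == 1]^2)
    s2 <- fit_independent_stage2(obs2, dm, fr2, cfg)
    expect_lte(s2$objective, zero_tpe_sse + 1e-8)
  }
})

test_that("goodness of fit matches hand-computed sums of squares", {
  gof <- goodness_of_fit(c(0, 2, 4), c(0, 2, 3))
  expect_equal(gof$r2, 0.875)            # SSres 1, SStot 8
  expect_equal(gof$rmse, sqrt(1 / 3), tolerance = 1e-4)
  perfect <- goodness_of_fit(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$rmse, 0)
  at_mean <- goodness_of_fit(c(1, 2, 3), rep(2, 3))
  expect_equal(at_mean$r2, 0)
  expect_warning(goodness_of_fit(c(2, 2, 2), c(1, 2, 3)), "zero variance")
})

test_that("bootstrap CIs are deterministic and collapse for identical subjects", {
  d <- drive_sequence(build_schedule("E1", "Hit"))
  m <- generate_cycle_traces("spe_only",
                             c(A_spe = 0.8, B_spe_drive = 1), d,
                             cycle_noise_sd = 1, n_subjects = 8, seed = 4)
  cfg <- fit_config(n_starts = 5)
  ci1 <- bootstrap_parameter_ci(m, "spe_only", d, cfg, n_boot = 40,
                                seed = 9)
  ci2 <- bootstrap_parameter_ci(m, "spe_only", d, cfg, n_boot = 40,
                                seed = 9)
  expect_identical(ci1, ci2)
  expect_true(all(ci1$lo95 <= ci1$hi95))

  # identical noiseless subjects: every resample refits the same series
  m0 <- generate_cycle_traces("spe_only",
                              c(A_spe = 0.8, B_spe_drive = 1), d,
                              cycle_noise_sd = 0, n_subjects = 5, seed = 1)
  ci0 <- bootstrap_parameter_ci(m0, "spe_only", d, cfg, n_boot = 25,
                                seed = 2)
  expect_equal(ci0$lo95, ci0$estimate, tolerance = 1e-3)
  expect_equal(ci0$hi95, ci0$estimate, tolerance = 1e-3)
  expect_error(bootstrap_parameter_ci(m0, "spe_only", d, cfg, n_boot = 0),
               "n_boot")
})

test_that("fit inputs are validated", {
  d <- drive_sequence(build_schedule("E1", "Hit"))
  expect_error(fit_spe_only(rep(0, 5), d), "cycle counts")
  d_all_masked <- make_drive(rep(1, 6), fit_mask = rep(0L, 6))
  expect_error(fit_spe_only(rep(0, 6), d_all_masked), "no cycles")
  expect_error(fit_interaction(rep(0, nrow(d)), d, estimate_gains = TRUE),
               "frozen")
})
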