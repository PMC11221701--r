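test_that("all eight designs have the documented block structure", {
  counts <- list(
    E1.Hit = c(baseline_nofb = 20, baseline_fb = 20, learning = 240,
               washout_nofb = 20, washout_fb = 20),
    E1.Miss = c(baseline_nofb = 20, baseline_fb = 20, learning = 240,
                washout_nofb = 20, washout_fb = 20),
    E2.J10 = c(baseline_nofb = 20, baseline_fb = 20, learning = 240,
               washout_nofb = 20, washout_fb = 20),
    E2.J20 = c(baseline_nofb = 20, baseline_fb = 20, learning = 240,
               washout_nofb = 20, washout_fb = 20),
    E3.Clamp = c(baseline_fb = 40, learning = 200, washout_nofb = 40,
                 washout_fb = 120),
    E3.ClampJump = c(baseline_fb = 40, learning = 200, washout_nofb = 40,
                     washout_fb = 120),
    E4.J10CCW = c(baseline_nofb = 20, baseline_fb = 20, learning = 240,
                  washout_fb = 20, washout_nofb = 20),
    E4.J30CW = c(baseline_fb = 40, learning = 200, washout_nofb = 40,
                 washout_fb = 120))
  designs <- list_designs()
  for (i in seq_len(nrow(designs))) {
    s <- build_schedule(designs$experiment[i], designs$group[i])
    key <- paste(designs$experiment[i], designs$group[i], sep = ".")
    got <- table(factor(s$block, levels = names(counts[[key]])))
    expect_equal(as.numeric(got), unname(counts[[key]]), info = key)
    # cycles tile the trial sequence and block boundaries respect them
    expect_equal(nrow(s) %% 10, 0, info = key)
    expect_equal(max(s$cycle) * 10, nrow(s), info = key)
    expect_true(all(tapply(s$block, s$cycle,
                           function(b) length(unique(b)) == 1)),
                info = key)
  }
  expect_error(build_schedule("E1", "nope"), "unknown design")
})

test_that("learning-trial perturbations match each design", {
  miss <- build_schedule("E1", "Miss")
  lm_ <- miss[miss$block == "learning", ]
  expect_true(all(lm_$jump_deg == 10))
  expect_true(all(lm_$feedback == "clamped"))
  expect_true(all(lm_$clamp_offset_deg == 0))
  expect_true(all(lm_$target_diameter_cm == 0.98))

  hit <- build_schedule("E1", "Hit")
  expect_true(all(hit$target_diameter_cm[hit$block == "learning"] == 4.6))

  clamp <- build_schedule("E3", "Clamp")
  expect_equal(nrow(clamp), 400)
  lc <- clamp[clamp$block == "learning", ]
  expect_true(all(lc$clamp_offset_deg == 30))
  expect_true(all(lc$jump_deg == 0))

  # no jump or clamp outside learning, anywhere
  for (i in seq_len(nrow(list_designs()))) {
    d <- list_designs()[i, ]
    s <- build_schedule(d$experiment, d$group)
    out <- s[s$block != "learning", ]
    expect_true(all(out$jump_deg == 0) && all(out$clamp_offset_deg == 0))
  }
})

test_that("target order is balanced over 4-trial windows and reproducible", {
  for (n in c(4, 8, 320)) {
    seq1 <- target_direction_sequence(n, seed = 1)
    wins <- matrix(seq1, nrow = 4)
    expect_true(all(apply(wins, 2, function(w)
      setequal(w, c(0, 90, 180, 270)))))
  }
  expect_identical(target_direction_sequence(12, seed = 7),
                   target_direction_sequence(12, seed = 7))
  expect_error(target_direction_sequence(10), "divisible by 4")
})

test_that("cursor hit/miss follows the chord geometry", {
  # 10 deg jump against the enlarged vs original target
  expect_equal(cursor_outcome(10, 0, 4.6, 10), "hit")
  expect_equal(cursor_outcome(10, 0, 0.98, 10), "miss")
  # co-jumped clamp: zero angular separation
  expect_equal(cursor_outcome(30, 30, 1.5, 10), "hit")
  # the deciding chord for a 10 deg separation is 2*10*sin(5 deg)
  expect_equal(2 * 10 * sin(5 * pi / 180), 1.7431, tolerance = 1e-4)

  # symmetry in the sign of (jump - clamp), monotone in diameter
  set.seed(42)
  for (i in 1:25) {
    j <- runif(1, -40, 40); c0 <- runif(1, -40, 40)
    d <- runif(1, 0.3, 5)
    expect_identical(cursor_outcome(j, c0, d), cursor_outcome(c0, j, d))
    if (cursor_outcome(j, c0, d) == "hit")
      expect_identical(cursor_outcome(j, c0, d * 2), "hit")
  }
  expect_error(cursor_outcome(10, 0, -1, 10), "positive")
})

test_that("drive indicators encode each group's error exposure", {
  drv <- function(e, g) drive_sequence(build_schedule(e, g))
  on_learning <- function(d, col) unique(d[[col]][d$block == "learning"])

  expect_equal(on_learning(drv("E1", "Hit"), "spe_on"), 1)
  expect_equal(on_learning(drv("E1", "Hit"), "tpe_on"), 0)
  expect_equal(on_learning(drv("E1", "Miss"), "tpe_on"), 1)
  expect_equal(on_learning(drv("E3", "ClampJump"), "spe_on"), 1)
  expect_equal(on_learning(drv("E3", "ClampJump"), "tpe_on"), 0)
  expect_equal(on_learning(drv("E2", "J10"), "spe_on"), 0)
  expect_equal(on_learning(drv("E2", "J10"), "tpe_on"), 1)

  # TPE-with-SPE groups have the two indicators coincide on learning
  for (g in list(c("E1", "Miss"), c("E3", "Clamp"))) {
    d <- drv(g[1], g[2])
    l <- d$block == "learning"
    expect_identical(d$spe_on[l], d$tpe_on[l])
  }
  # no SPE anywhere for the veridical/no-SPE experiments
  for (g in list(c("E2", "J10"), c("E2", "J20"),
                 c("E4", "J10CCW"), c("E4", "J30CW"))) {
    expect_true(all(drv(g[1], g[2])$spe_on == 0))
  }
  # drives silent outside learning; mask drops exactly the fb washout
  d <- drv("E1", "Miss")
  expect_true(all(d$spe_on[d$block != "learning"] == 0))
  expect_true(all(d$tpe_on[d$block != "learning"] == 0))
  expect_identical(d$fit_mask == 0, d$block == "washout_fb")
})

test_that("schedule CSV serialization has the documented columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_schedule_csv(build_schedule("E1", "Miss"), path, subject = 3)
  got <- read.csv(path)
  expect_identical(names(got),
                   c("subject", "experiment", "group", "trial", "cycle",
                     "block", "target_dir_deg", "jump_deg",
                     "clamp_offset_deg", "target_diameter_cm", "feedback"))
  expect_equal(nrow(got), 320)
  expect_true(all(got$subject == 3))
})
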