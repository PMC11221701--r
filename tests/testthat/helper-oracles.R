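# Shared fixtures and independent oracles for the fitting tests.

# A minimal drive data frame from raw indicator vectors.
make_drive <- function(spe_on, tpe_on = rep(0L, length(spe_on)),
                       fit_mask = rep(1L, length(spe_on))) {
  data.frame(cycle = seq_along(spe_on), block = "learning",
             spe_on = spe_on, tpe_on = tpe_on, fit_mask = fit_mask)
}

# Brute-force recursion, written independently of the package internals:
# iterates the state update with explicit indexing.
brute_spe_trace <- function(A, B, spe_on, x0 = 0) {
  x <- x0
  out <- numeric(length(spe_on))
  for (k in seq_along(spe_on)) {
    out[k] <- x
    x <- A * x + B * spe_on[k]
  }
  out
}

# Exhaustive grid-search oracle for the two-parameter SPE-only fit.
# For fixed A the trace is linear in B (x0 = 0), so each A needs one
# unit-drive simulation.
grid_search_spe <- function(observed, drive, bound,
                            a_step = 0.01, b_step = 0.05) {
  use <- drive$fit_mask == 1 & !is.na(observed)
  a_grid <- seq(0, 1, by = a_step)
  b_grid <- seq(0, bound, by = b_step)
  best <- list(sse = Inf)
  for (A in a_grid) {
    u <- brute_spe_trace(A, 1, drive$spe_on)[use]
    sse <- colSums((observed[use] - outer(u, b_grid))^2)
    i <- which.min(sse)
    if (sse[i] < best$sse)
      best <- list(A = A, B = b_grid[i], sse = sse[i],
                   # objective spread across one neighbouring grid step,
                   # used as the comparison slack
                   step_slack = max(abs(diff(sse))[max(i - 1, 1):
                                                     min(i, length(sse) - 1)]))
  }
  best
}

# Random box-interior parameter draw.
draw_params <- function(bound = 10) {
  c(A = runif(1, 0.05, 0.95), B = runif(1, 0.1, 0.9) * bound / 2)
}
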