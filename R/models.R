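# Forward dynamics of the trial-by-trial (cycle-by-cycle) learning models.
#
# All models run at one update per 10-trial cycle, the resolution of the
# fitted data. State x(n) is the predicted hand deviation (deg) on cycle n;
# the update from cycle n to n+1 uses the drive present on cycle n. Because
# the cursor clamp holds the error constant, the learning-rate x error
# product is a single lumped drive parameter in degrees per cycle.

.check_retention <- function(A, name) {
  if (!is.finite(A) || A < 0 || A > 1)
    stop(name, " must lie in [0, 1]", call. = FALSE)
}

.check_drive_param <- function(B, name, bound) {
  if (!is.finite(B) || B < 0 || B > bound)
    stop(name, " must lie in [0, ", bound, "]", call. = FALSE)
}

.drive_vec <- function(drive, col) {
  if (is.data.frame(drive)) drive[[col]] else drive
}

#' Simulate the SPE-driven learning process
#'
#' Single-process state-space learner
#' `x(n+1) = A * x(n) + B_drive * spe_on(n)`, with retention factor `A`
#' and lumped error drive `B_drive` (degrees/cycle) applied on cycles where
#' a sensory prediction error is present.
#'
#' @param A Retention factor in \[0, 1\].
#' @param B_drive Lumped drive (learning rate x constant error) in degrees
#'   per cycle; applied when `spe_on` is 1.
#' @param drive A drive data frame from [drive_sequence()] or a 0/1 vector
#'   of SPE presence per cycle.
#' @param x0 Initial state in degrees at the first cycle.
#' @param drive_bound Upper bound used to validate `B_drive`.
#' @return Numeric vector of states, one per cycle.
#' @export
simulate_spe <- function(A, B_drive, drive, x0 = 0, drive_bound = Inf) {
  .check_retention(A, "A")
  .check_drive_param(B_drive, "B_drive", drive_bound)
  stopifnot(is.finite(x0))
  spe_on <- .drive_vec(drive, "spe_on")
  n <- length(spe_on)
  x <- numeric(n)
  x[1] <- x0
  for (k in seq_len(n - 1L))
    x[k + 1L] <- A * x[k] + B_drive * spe_on[k]
  x
}

#' Simulate the Independent Error model
#'
#' Two additive implicit processes: an SPE-driven state and a TPE-driven
#' state, each with its own retention factor and lumped drive, updated as
#' `x_spe(n+1) = A_spe * x_spe(n) + B_spe_drive * spe_on(n)` and
#' `x_tpe(n+1) = A_tpe * x_tpe(n) + B_tpe_drive * tpe_on(n)`; the net motor
#' output is their sum. With `retention = "net"` the SPE process instead
#' retains the net state (`A_spe * x_net(n)`), an alternative printed form
#' of the update; the default keeps each process self-retaining, which
#' preserves the additive decomposition.
#'
#' @param A_spe,B_spe_drive SPE-process retention and lumped drive.
#' @param A_tpe,B_tpe_drive TPE-process retention and lumped drive.
#' @param drive Drive data frame with `spe_on` and `tpe_on` columns (see
#'   [drive_sequence()]), or a list with those elements.
#' @param x0_spe,x0_tpe Initial states in degrees.
#' @param retention `"own"` (each process retains its own state, default) or
#'   `"net"` (SPE process retains the net state).
#' @param drive_bound Upper bound used to validate the drive parameters.
#' @return A data frame with columns cycle, x_spe, x_tpe, x_net.
#' @export
simulate_independent <- function(A_spe, B_spe_drive, A_tpe, B_tpe_drive,
                                 drive, x0_spe = 0, x0_tpe = 0,
                                 retention = c("own", "net"),
                                 drive_bound = Inf) {
  retention <- match.arg(retention)
  .check_retention(A_spe, "A_spe"); .check_retention(A_tpe, "A_tpe")
  .check_drive_param(B_spe_drive, "B_spe_drive", drive_bound)
  .check_drive_param(B_tpe_drive, "B_tpe_drive", drive_bound)
  spe_on <- .drive_vec(drive, "spe_on")
  tpe_on <- if (is.data.frame(drive) || is.list(drive)) drive[["tpe_on"]]
            else stop("drive must carry spe_on and tpe_on", call. = FALSE)
  n <- length(spe_on)
  x_spe <- x_tpe <- numeric(n)
  x_spe[1] <- x0_spe; x_tpe[1] <- x0_tpe
  for (k in seq_len(n - 1L)) {
    ret_state <- if (retention == "own") x_spe[k] else x_spe[k] + x_tpe[k]
    x_spe[k + 1L] <- A_spe * ret_state + B_spe_drive * spe_on[k]
    x_tpe[k + 1L] <- A_tpe * x_tpe[k] + B_tpe_drive * tpe_on[k]
  }
  data.frame(cycle = seq_len(n), x_spe = x_spe, x_tpe = x_tpe,
             x_net = x_spe + x_tpe)
}

#' Simulate the Interaction model
#'
#' A single SPE-driven state whose retention and drive are gain-modulated by
#' task outcome: `x(n+1) = gA(n) * A * x(n) + gB(n) * B_drive * spe_on(n)`,
#' where the gains equal 1 on cycles where a TPE is present and take the
#' supplied values `G_A`, `G_B` on TPE-absent cycles. With both gains at 1
#' the model is identical to [simulate_spe()].
#'
#' @param A,B_drive Retention factor and lumped SPE drive.
#' @param G_A,G_B Gains applied to retention and drive on TPE-absent cycles.
#' @param drive Drive data frame with `spe_on` and `tpe_on` columns.
#' @param x0 Initial state in degrees.
#' @param drive_bound Upper bound used to validate `B_drive`.
#' @return Numeric vector of states, one per cycle.
#' @export
simulate_interaction <- function(A, B_drive, G_A, G_B, drive, x0 = 0,
                                 drive_bound = Inf) {
  .check_retention(A, "A")
  .check_drive_param(B_drive, "B_drive", drive_bound)
  if (G_A < 0 || G_B < 0) stop("gains must be non-negative", call. = FALSE)
  spe_on <- .drive_vec(drive, "spe_on")
  tpe_on <- drive[["tpe_on"]]
  n <- length(spe_on)
  x <- numeric(n)
  x[1] <- x0
  for (k in seq_len(n - 1L)) {
    gA <- if (tpe_on[k] == 1) 1 else G_A
    gB <- if (tpe_on[k] == 1) 1 else G_B
    x[k + 1L] <- gA * A * x[k] + gB * B_drive * spe_on[k]
  }
  x
}

#' Fixed point of a constant-drive learning process
#'
#' Under constant drive the recursion `x(n+1) = A x(n) + B` converges to
#' `B / (1 - A)`.
#'
#' @param A Retention factor, `0 <= A < 1`.
#' @param B_drive Lumped drive in degrees per cycle.
#' @return Asymptotic state in degrees.
#' @export
asymptote <- function(A, B_drive) {
  if (!is.finite(A) || A < 0 || A >= 1)
    stop("A must lie in [0, 1) for a finite asymptote", call. = FALSE)
  B_drive / (1 - A)
}

#' Write a simulated state trace as CSV
#'
#' @param trace Data frame from [simulate_independent()], or a numeric state
#'   vector (stored as `x_net`, with `x_spe = x_net` and `x_tpe = 0`).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  if (!is.data.frame(trace))
    trace <- data.frame(cycle = seq_along(trace), x_spe = trace,
                        x_tpe = 0, x_net = trace)
  utils::write.csv(trace[, c("cycle", "x_spe", "x_tpe", "x_net")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
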