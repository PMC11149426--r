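#' Construct the tendon-driven eye plant
#'
#' Binds a muscle geometry to physical parameters and pre-computes the
#' reference cable path lengths and the holding command at the straight-ahead
#' fixation. The holding command is the minimum-norm set of six commanded
#' shortenings that nulls the net tendon torque at r = (0,0,0) while keeping
#' every tension above the slack floor; all control signals handled by the
#' package are expressed relative to this baseline, so a plant at rest under
#' zero (relative) command sits still at the reference fixation.
#'
#' @param geometry an [eye_geometry()].
#' @param params a [plant_params()].
#' @return an object of class `eye_plant`.
#' @export
eye_plant <- function(geometry = eye_geometry(), params = plant_params()) {
  plant <- structure(list(geometry = geometry, params = params,
                          L0 = NULL, u_fix0 = rep(0, 6)),
                     class = "eye_plant")
  paths0 <- muscle_paths(plant, c(0, 0, 0))
  plant$L0 <- paths0$length
  plant$u_fix0 <- fixation_command(plant, c(0, 0, 0), absolute = TRUE)
  plant
}

#' @export
print.eye_plant <- function(x, ...) {
  cat("<eye_plant> 6-tendon rigid-body eye, globe", x$geometry$radius, "mm\n")
  t0 <- tendon_tension(x, c(0, 0, 0), rep(0, 6))
  cat("  static tensions at (0,0,0) [N]:",
      paste(sprintf("%s=%.3f", x$geometry$muscles, t0), collapse = " "), "\n")
  invisible(x)
}

#' Cable pulling geometry at an eye orientation
#'
#' Rotates the insertion points by the eye orientation and returns, per
#' muscle, the straight cable segment from insertion to anchor (orbital
#' origin, or pulley for the obliques): unit pulling direction, current path
#' length, and the torque moment vector (insertion point x direction).
#'
#' @param plant an [eye_plant()].
#' @param r eye orientation, rotation vector (rad/2).
#' @return list with `point` (6 x 3, rotated insertions, mm), `dir` (6 x 3
#'   unit pulling directions), `length` (6, mm), `moment` (6 x 3, mm).
#' @export
muscle_paths <- function(plant, r) {
  g <- plant$geometry
  R <- rot_matrix(r)
  p <- g$radius * g$insertion %*% t(R)
  v <- g$attach - p
  len <- sqrt(rowSums(v^2))
  if (any(len <= 1e-9)) stop("degenerate muscle path (zero length)", call. = FALSE)
  d <- v / len
  m <- cbind(p[, 2] * d[, 3] - p[, 3] * d[, 2],
             p[, 3] * d[, 1] - p[, 1] * d[, 3],
             p[, 1] * d[, 2] - p[, 2] * d[, 1])
  dimnames(p) <- dimnames(d) <- dimnames(m) <- list(g$muscles, c("x", "y", "z"))
  list(point = p, dir = d, length = len, moment = m)
}

#' Tendon tensions under a command
#'
#' Pull-only linear spring law: `T = max(0, T_pre + k * (stretch + u))`,
#' where stretch is the change in cable path length relative to the
#' straight-ahead fixation and `u` is the total commanded shortening
#' (holding command plus relative command). Negative values are clamped to
#' zero: a cable can go slack but can never push.
#'
#' @param plant an [eye_plant()].
#' @param r eye orientation (rad/2).
#' @param u relative commanded shortenings, length 6 (mm); the plant's own
#'   holding command at (0,0,0) is added internally.
#' @param absolute if TRUE, `u` is interpreted as the total command and the
#'   holding command is not added.
#' @return named numeric length 6, tensions in N.
#' @export
tendon_tension <- function(plant, r, u, absolute = FALSE) {
  pp <- plant$params
  stretch <- muscle_paths(plant, r)$length - plant$L0
  u_tot <- if (absolute) u else plant$u_fix0 + u
  setNames(pmax(0, pp$pretension + pp$stiffness * (stretch + u_tot)),
           plant$geometry$muscles)
}

#' Net torque on the globe
#'
#' Sum over muscles of (rotated insertion) x (tension * pulling direction),
#' minus the viscous damping torque; N mm, head frame.
#'
#' @param plant an [eye_plant()].
#' @param state list with `r` (rotation vector) and `w` (angular velocity).
#' @param u relative commands, length 6 (mm).
#' @param absolute see [tendon_tension()].
#' @return length-3 torque vector (N mm).
#' @export
net_torque <- function(plant, state, u, absolute = FALSE) {
  mp <- muscle_paths(plant, state$r)
  tn <- tendon_tension(plant, state$r, u, absolute = absolute)
  drop(tn %*% mp$moment) - plant$params$damping * state$w
}

#' Eye state
#'
#' @param r rotation vector (rad/2).
#' @param w angular velocity (rad/s).
#' @return list of class `eye_state`.
#' @export
eye_state <- function(r = c(0, 0, 0), w = c(0, 0, 0)) {
  structure(list(r = as_rotvec(r), w = as.numeric(w)), class = "eye_state")
}

plant_accel <- function(plant, state, u, absolute = FALSE) {
  tau <- net_torque(plant, state, u, absolute = absolute)
  R <- rot_matrix(state$r)
  Ih <- R %*% diag(plant$params$inertia) %*% t(R)
  gyro <- cross3(state$w, drop(Ih %*% state$w))
  drop(solve(Ih, 1000 * tau - gyro))
}

#' Advance the plant by one integration step
#'
#' Pure-R reference propagator for the Newton-Euler dynamics
#' `I(r) wdot = 1000 tau - w x (I(r) w)` (the factor converts N mm / kg mm^2
#' to rad/s^2), with the orientation advanced through the exact kinematic
#' map of [rdot_from_omega()]. Used for validation and small-scale oracles;
#' [simulate_plant()] runs the identical scheme in compiled code.
#'
#' @param plant an [eye_plant()].
#' @param state an [eye_state()].
#' @param u relative commands held constant over the step (mm).
#' @param method `"rk4"` (default, classical Runge-Kutta) or `"euler"`.
#' @param dt step length (s); defaults to the plant's 1 ms.
#' @return the new `eye_state`.
#' @export
plant_step <- function(plant, state, u, method = c("rk4", "euler"), dt = NULL) {
  method <- match.arg(method)
  if (is.null(dt)) dt <- plant$params$dt
  f <- function(r, w) {
    st <- list(r = r, w = w)
    list(rdot = rdot_from_omega(r, w), wdot = plant_accel(plant, st, u))
  }
  r <- state$r; w <- state$w
  k1 <- f(r, w)
  if (method == "euler") {
    return(eye_state(r + dt * k1$rdot, w + dt * k1$wdot))
  }
  k2 <- f(r + dt / 2 * k1$rdot, w + dt / 2 * k1$wdot)
  k3 <- f(r + dt / 2 * k2$rdot, w + dt / 2 * k2$wdot)
  k4 <- f(r + dt * k3$rdot, w + dt * k3$wdot)
  eye_state(r + dt / 6 * (k1$rdot + 2 * k2$rdot + 2 * k3$rdot + k4$rdot),
            w + dt / 6 * (k1$wdot + 2 * k2$wdot + 2 * k3$wdot + k4$wdot))
}

muscle_cols <- function(prefix) paste0(prefix, c("LR", "MR", "SR", "IR", "SO", "IO"))

#' Simulate the plant under a control signal
#'
#' Drives the compiled Newton-Euler integrator with a 6 x T matrix of
#' per-muscle commands sampled at 1 ms (commanded cable shortening in mm,
#' relative to the straight-ahead holding command, zero-order hold). The
#' result is deterministic: identical inputs give bit-identical
#' trajectories.
#'
#' @param plant an [eye_plant()].
#' @param controls 6 x T numeric matrix (rows LR, MR, SR, IR, SO, IO), or a
#'   length-6 vector recycled over `t_ms` steps.
#' @param x0 initial [eye_state()].
#' @param t_ms horizon in ms when `controls` is a vector.
#' @return an `eye_trajectory`: a data frame with one row per ms (t = 0..T)
#'   and columns `t_ms`, `rx ry rz` (rad/2), `wx wy wz` (rad/s),
#'   `drx dry drz` (rad/2 per s), `u_*` (mm) and `T_*` (N).
#' @export
simulate_plant <- function(plant, controls, x0 = eye_state(), t_ms = NULL) {
  if (!is.matrix(controls)) {
    stopifnot(!is.null(t_ms))
    controls <- matrix(as.numeric(controls), nrow = 6, ncol = t_ms)
  }
  stopifnot(nrow(controls) == 6)
  g <- plant$geometry; pp <- plant$params
  out <- cpp_simulate(controls, x0$r, x0$w, g$insertion, g$attach, g$radius,
                      plant$L0, plant$u_fix0, pp$stiffness, pp$pretension,
                      pp$inertia, pp$damping, pp$dt)
  N <- ncol(controls)
  u_rec <- t(controls)[c(seq_len(N), N), , drop = FALSE]
  traj <- data.frame(t_ms = 0:N, out$r, out$w, out$rdot, u_rec, out$tension)
  names(traj) <- c("t_ms", "rx", "ry", "rz", "wx", "wy", "wz",
                   "drx", "dry", "drz", muscle_cols("u_"), muscle_cols("T_"))
  class(traj) <- c("eye_trajectory", "data.frame")
  attr(traj, "dt") <- pp$dt
  traj
}

#' Static command holding a fixation
#'
#' Solves for the minimum-norm six-muscle command whose tensions produce
#' zero net torque at the requested orientation (torque is linear in the
#' commands while all cables are taut, so the minimum-norm solution comes
#' from the normal equations of the 3 x 6 moment-arm map). If the
#' unconstrained solution would push a tension below the slack floor, that
#' muscle is pinned at the floor and the remaining muscles are re-solved
#' (small active-set iteration); a fixation needing more than three pinned
#' cables, or leaving the floor unattainable, fails.
#'
#' @param plant an [eye_plant()].
#' @param r_fix orientation to hold (rad/2).
#' @param absolute if TRUE return the total command; otherwise relative to
#'   the (0,0,0) holding command.
#' @return named numeric length 6 (mm).
#' @export
fixation_command <- function(plant, r_fix, absolute = FALSE) {
  pp <- plant$params
  mp <- muscle_paths(plant, r_fix)
  stretch <- mp$length - plant$L0
  M <- t(mp$moment)                      # 3 x 6
  T_floor <- pp$tension_floor
  pinned <- rep(FALSE, 6)
  u_abs <- rep(0, 6)
  for (iter in 1:4) {
    free <- which(!pinned)
    # pinned muscles sit exactly at the floor tension
    u_abs[pinned] <- (T_floor - pp$pretension) / pp$stiffness - stretch[pinned]
    tens_pin <- rep(0, 6); tens_pin[pinned] <- T_floor
    A <- pp$stiffness * M[, free, drop = FALSE]
    b <- -drop(M[, free, drop = FALSE] %*%
                 (pp$pretension + pp$stiffness * stretch[free])) -
         drop(M[, pinned, drop = FALSE] %*% tens_pin[pinned])
    if (length(free) < 3)
      stop(sprintf("fixation at (%.3f, %.3f, %.3f) infeasible: too many slack cables",
                   r_fix[1], r_fix[2], r_fix[3]), call. = FALSE)
    sol <- try(drop(t(A) %*% solve(A %*% t(A), b)), silent = TRUE)
    if (inherits(sol, "try-error"))
      stop(sprintf("fixation at (%.3f, %.3f, %.3f) infeasible: degenerate moment map",
                   r_fix[1], r_fix[2], r_fix[3]), call. = FALSE)
    u_abs[free] <- sol
    tens <- pp$pretension + pp$stiffness * (stretch + u_abs)
    viol <- which(!pinned & tens < T_floor - 1e-9)
    if (length(viol) == 0) {
      u_abs <- setNames(u_abs, plant$geometry$muscles)
      return(if (absolute) u_abs else u_abs - plant$u_fix0)
    }
    pinned[viol[which.min(tens[viol])]] <- TRUE
  }
  stop(sprintf("fixation at (%.3f, %.3f, %.3f) infeasible: tension below slack floor",
               r_fix[1], r_fix[2], r_fix[3]), call. = FALSE)
}
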