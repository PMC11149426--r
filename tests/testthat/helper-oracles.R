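# Independent oracles and shared fixtures for the test suite.

# ---- unit-quaternion oracle (independent of the rotation-vector algebra) ----
# q = (w, x, y, z); a rotation vector r maps to q = (1, r) / sqrt(1 + |r|^2).

q_from_r <- function(r) {
  s <- sqrt(1 + sum(r^2))
  c(1, r) / s
}

q_mult <- function(a, b) {
  c(a[1] * b[1] - sum(a[2:4] * b[2:4]),
    a[1] * b[2:4] + b[1] * a[2:4] +
      c(a[3] * b[4] - a[4] * b[3],
        a[4] * b[2] - a[2] * b[4],
        a[2] * b[3] - a[3] * b[2]))
}

q_conj <- function(q) c(q[1], -q[2:4])

r_from_q <- function(q) q[2:4] / q[1]

# angular velocity through the quaternion derivative: omega = 2 qdot x q^-1
# (vector part), with qdot from Richardson-extrapolated central differences
# (O(h^4) truncation with rounding ~ eps/h, so h = 1e-4 leaves ~1e-12 error).
omega_oracle <- function(r, rdot, h = 1e-4) {
  cdiff <- function(hh) (q_from_r(r + hh * rdot) - q_from_r(r - hh * rdot)) / (2 * hh)
  qd <- (4 * cdiff(h / 2) - cdiff(h)) / 3
  q0 <- q_from_r(r)
  w <- 2 * q_mult(qd, q_conj(q0))  # unit quaternion: conjugate = inverse
  w[2:4]
}

random_rotvec <- function(max_norm = 0.4) {
  v <- rnorm(3)
  v / sqrt(sum(v^2)) * runif(1, 0, max_norm)
}

# ---- shared plant and expensive shared runs (computed once per session) ----

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

default_plant <- function() cached("plant", eye_plant())

# 30-saccade continuous paradigm at desk scale: shared by the accuracy
# criterion and several qualitative checks.
continuous_run <- function() {
  cached("continuous30", run_continuous(
    default_plant(), paradigm_config("continuous", n = 30, seed = 11)))
}

# small paradigm runs shared by the experiment and i/o tests
tiny_zero <- function() {
  cached("zero4", run_zero_initial(
    default_plant(), paradigm_config("zero_initial", n = 4, seed = 21)))
}
tiny_cont <- function() {
  cached("cont4", run_continuous(
    default_plant(), paradigm_config("continuous", n = 4, seed = 22)))
}

# a small battery of cardinal-direction optimal saccades at fixed amplitudes
cardinal_saccades <- function(amp_deg) {
  key <- paste0("cardinal", amp_deg)
  cached(key, {
    p <- default_plant()
    a2 <- tan(amp_deg / 2 * pi / 180)
    list(right = optimal_saccade(p, saccade_goal(0, -a2)),
         left  = optimal_saccade(p, saccade_goal(0,  a2)),
         up    = optimal_saccade(p, saccade_goal(-a2, 0)),
         down  = optimal_saccade(p, saccade_goal( a2, 0)))
  })
}

peak_speed <- function(sac) {
  tr <- sac$trajectory
  max(sqrt(tr$wx^2 + tr$wy^2 + tr$wz^2)) * 180 / pi
}

# Listing plane of the pre-stimulation vertical movements (how the
# stimulation experiment defines its reference plane).
vertical_listing_fit <- function() {
  cached("vertical_lp", {
    p <- default_plant()
    rs <- lapply(c(-12, -6, 6, 12), function(e) {
      s <- optimal_saccade(p, saccade_goal(-tan(e / 2 * pi / 180), 0))
      as.matrix(s$trajectory[, c("rx", "ry", "rz")])
    })
    fit_listing_plane(do.call(rbind, rs))
  })
}

# minimum-jerk gaze trajectory along the azimuth axis, as an analytic
# fixture: amplitude A deg, duration D ms, 1 ms sampling.
minimum_jerk_trajectory <- function(A = 20, D = 100) {
  tt <- 0:D
  s <- tt / D
  az <- A * (10 * s^3 - 15 * s^4 + 6 * s^5)
  r <- t(vapply(az, function(a) rotvec_from_gaze(a, 0), numeric(3)))
  rdot <- rbind(diff(r), 0) / 1e-3
  w <- t(vapply(seq_along(tt), function(i) omega_from_rdot(r[i, ], rdot[i, ]),
                numeric(3)))
  traj <- data.frame(t_ms = tt, rx = r[, 1], ry = r[, 2], rz = r[, 3],
                     wx = w[, 1], wy = w[, 2], wz = w[, 3],
                     drx = rdot[, 1], dry = rdot[, 2], drz = rdot[, 3])
  for (cn in c(bioeye:::muscle_cols("u_"), bioeye:::muscle_cols("T_")))
    traj[[cn]] <- 0
  class(traj) <- c("eye_trajectory", "data.frame")
  attr(traj, "dt") <- 1e-3
  traj
}

# fabricate a minimal saccade_dataset from control matrices + trajectories,
# for analysis-module tests that do not need the optimizer
fake_dataset <- function(records) {
  structure(list(records = records, paradigm = "synthetic",
                 config = list(), n = length(records)),
            class = "saccade_dataset")
}
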