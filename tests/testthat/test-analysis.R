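test_that("saccade metrics recover amplitude, direction and the analytic peak speed", {
  traj <- minimum_jerk_trajectory(A = 20, D = 100)
  m <- saccade_metrics(traj, D = 100)
  expect_equal(m$R, 20, tolerance = 1e-9)
  expect_equal(m$Phi, 0, tolerance = 1e-9)
  # minimum-jerk peak speed 1.875 * A / D, discretization-limited agreement
  expect_equal(m$V_pk, 1.875 * 20 / 0.1, tolerance = 1e-3)
  expect_equal(m$V_pk_H, m$V_pk, tolerance = 1e-2)
  expect_lt(m$V_pk_V, 1)
  # threshold-rule onset/offset bracket the analytic movement
  m2 <- saccade_metrics(traj, D = NULL, threshold = 20)
  expect_lt(m2$onset, 20)
  expect_gt(m2$offset, 80)
  expect_equal(m2$R, 20, tolerance = 0.1)
})

test_that("rotational and planar amplitude measures agree inside the range", {
  set.seed(60)
  for (i in 1:200) {
    g1 <- runif(2, -27, 27); g2 <- runif(2, -27, 27)
    r_on <- rotvec_from_gaze(g1[1], g1[2])
    r_G <- rotvec_from_gaze(g2[1], g2[2])
    R_rot <- rot_angle(rot_between(r_on, r_G))
    R_pla <- sqrt(sum((g2 - g1)^2))
    if (R_pla < 1) next
    # across the full +-27 deg field the two measures stay within 5%; the
    # residual is the torsion of relative rotations between torsion-free
    # eccentric orientations (non-commutativity), so exact agreement only
    # holds from the origin
    expect_lt(abs(R_rot - R_pla) / R_pla, 0.05)
  }
  expect_equal(rot_angle(rot_between(c(0, 0, 0), rotvec_from_gaze(10, 0))), 10,
               tolerance = 1e-12)
})

test_that("accuracy regression recovers constructed stimulus-response gains", {
  # perfect responses: unit slopes, zero offsets, r^2 = 1
  d <- data.frame(T_H = seq(-30, 30, 5), T_V = seq(-20, 20, length.out = 13))
  d$theta_H <- d$T_H; d$phi_V <- d$T_V
  f <- accuracy_regression(d)
  expect_equal(c(f$a, f$b, f$c, f$d), c(0, 1, 0, 1), tolerance = 1e-12)
  expect_equal(c(f$r2_H, f$r2_V), c(1, 1))
  # gain-0.9 responses recover slope 0.9
  d$theta_H <- 0.9 * d$T_H; d$phi_V <- 0.9 * d$T_V + 1
  f <- accuracy_regression(d)
  expect_equal(f$b, 0.9, tolerance = 1e-12)
  expect_equal(f$d, 0.9, tolerance = 1e-12)
  expect_equal(f$c, 1, tolerance = 1e-12)
})

test_that("main-sequence fits are exact on noise-free synthetic data", {
  e <- 20; f <- 2; k <- 0; m <- 1.6
  R <- seq(2, 40, 2)
  met <- data.frame(R = R, D = e + f * R,
                    V_pk = 1000 * (k + m * R) / (e + f * R))
  fit <- main_sequence_fit(met)
  expect_equal(c(fit$e, fit$f, fit$k, fit$m), c(e, f, k, m), tolerance = 1e-9)
  expect_equal(fit$saturation, 1000 * m / f, tolerance = 1e-9)
  # the amplitude -> peak-velocity prediction saturates at m/f
  expect_equal(predict_vpk(1e9, fit), fit$saturation, tolerance = 1e-3)
  expect_equal(predict_vpk(10, fit),
               (m / (e / 1000)) / (1 / 10 + (f / 1000) / (e / 1000)),
               tolerance = 1e-9)
})

test_that("curvature index matches its geometric constructions", {
  # straight segments in any direction are exactly straight
  for (phi in c(0, 37, 90, 141, 270)) {
    tt <- seq(0, 1, length.out = 200)
    trace <- cbind(10 * tt * cos(phi * pi / 180), 10 * tt * sin(phi * pi / 180))
    cv <- curvature(trace)
    expect_equal(cv$C, 0, tolerance = 1e-12)
    expect_equal(cv$class, "straight")
  }
  # rightward semicircle, arc in the first quadrant -> C = -0.5
  th <- seq(pi, 0, length.out = 2001)
  semi <- cbind(5 + 5 * cos(th), 5 * sin(th))
  expect_equal(curvature(semi)$C, -0.5, tolerance = 1e-6)
  expect_equal(curvature(semi)$class, "curved")
  # reflection about the movement axis flips the sign
  expect_equal(curvature(cbind(semi[, 1], -semi[, 2]))$C, 0.5, tolerance = 1e-6)
  # single bump of height h over run A -> |C| = h/A
  tt <- seq(0, 1, length.out = 1001)
  bump <- cbind(8 * tt, 0.4 * sin(pi * tt))
  expect_equal(curvature(bump)$C, -0.4 / 8, tolerance = 1e-6)
  # invariance under global rotation + translation of the trace
  ang <- 33 * pi / 180
  Rm <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  moved <- sweep(bump %*% t(Rm), 2, c(-3, 7), "+")
  expect_equal(curvature(moved)$C, curvature(bump)$C, tolerance = 1e-9)
})

test_that("Listing-plane fits recover plane parameters and noise level", {
  set.seed(70)
  n <- 10000
  ry <- runif(n, -0.3, 0.3); rz <- runif(n, -0.3, 0.3)
  alpha <- -0.116; beta <- -0.020
  r_exact <- cbind(alpha * ry + beta * rz, ry, rz)
  f <- fit_listing_plane(r_exact)
  expect_equal(c(f$alpha, f$beta), c(alpha, beta), tolerance = 1e-12)
  expect_equal(f$sigma, 0)
  expect_equal(f$tilt_deg, atan(alpha) * 180 / pi, tolerance = 1e-12)
  # Gaussian torsional noise of sd s is recovered within 5%
  s <- 0.0075
  r_noisy <- r_exact + cbind(rnorm(n, 0, s), 0, 0)
  fn <- fit_listing_plane(r_noisy)
  expect_lt(abs(fn$sigma - s) / s, 0.05)
  # order invariance
  fp <- fit_listing_plane(r_noisy[sample(n), ])
  expect_equal(fp$sigma, fn$sigma, tolerance = 1e-12)
  expect_equal(fp$alpha, fn$alpha, tolerance = 1e-12)
})

test_that("position-gain regression recovers constructed coefficients", {
  set.seed(80)
  n <- 200
  R <- runif(n, 6, 30)
  h_rel <- runif(n, -20, 20)          # contralateral-positive start position
  zs <- function(z) (z - mean(z)) / sd(z)
  # the regression standardizes the response, so the recoverable
  # coefficients are the construction weights divided by sd(response)
  v_clean <- 0.7 * zs(R) + 0.4 * zs(h_rel)
  v_noisy <- v_clean + rnorm(n, 0, 0.05)
  met <- data.frame(R = R, H_on = -h_rel, Phi = 0, V_pk = v_noisy * 50 + 300)
  fit <- position_gain_regression(met)
  expect_equal(fit$g_R2, 0.7 / sd(v_noisy), tolerance = 0.05)
  expect_equal(fit$g_Hon, 0.4 / sd(v_noisy), tolerance = 0.05)
  expect_lt(fit$p_added, 1e-6)
  expect_gt(fit$r2_2, fit$r2_1)
  # noise-free data are recovered exactly (up to the response scaling)
  met$V_pk <- v_clean * 50 + 300
  fit0 <- position_gain_regression(met)
  expect_equal(fit0$g_R2, 0.7 / sd(v_clean), tolerance = 1e-9)
  expect_equal(fit0$g_Hon, 0.4 / sd(v_clean), tolerance = 1e-9)
  # zero-variance regressor is an explicit error
  met$H_on <- 0
  expect_error(position_gain_regression(met), "zero-variance")
})

test_that("common-source predictions reduce to the vectorial main sequence", {
  fit <- main_sequence_fit(data.frame(R = seq(2, 40, 2),
                                      D = 20 + 2 * seq(2, 40, 2),
                                      V_pk = 1000 * 1.6 * seq(2, 40, 2) /
                                             (20 + 2 * seq(2, 40, 2))))
  dH <- 12
  expect_equal(common_source_prediction(dH, 0, fit, "H"),
               predict_vpk(dH, fit), tolerance = 1e-12)
  # fixed component, varying direction: pure cosine scaling
  for (Phi in c(20, 45, 60)) {
    expect_equal(common_source_prediction(dH, Phi, fit, "H") /
                   common_source_prediction(dH, 0, fit, "H"),
                 cos(Phi * pi / 180), tolerance = 1e-12)
    expect_equal(common_source_prediction(dH, Phi, fit, "V") /
                   common_source_prediction(dH, 90, fit, "V"),
                 sin(Phi * pi / 180), tolerance = 1e-12)
  }
})

test_that("synergy correlations hit +-1 for identical and negated commands", {
  traj <- minimum_jerk_trajectory(A = 10, D = 60)
  base <- sin(seq(0, pi, length.out = 60))
  u <- rbind(LR = base, MR = -base, SR = base, IR = 0.5 * base,
             SO = -0.3 * base, IO = base + 0.2)
  rec <- structure(list(goal = c(0, 0, -0.1), start = c(0, 0, 0),
                        end = c(0, 0, -0.1), D = 60, amplitude = 10,
                        controls = u, trajectory = traj,
                        endpoint_error_deg = 0), class = "saccade_record")
  sy <- synergy_correlations(fake_dataset(list(rec, rec)))
  expect_equal(sy$r[["LR-MR"]], c(-1, -1))
  expect_equal(sy$r[["SR-IO"]], c(1, 1))   # scaled + offset copies still r = 1
  expect_equal(sy$r[["SO-IO"]], c(-1, -1))
})

test_that("component coupling returns +1 for proportional components", {
  # oblique minimum-jerk movement: vertical component proportional to horizontal
  tt <- 0:100; s <- tt / 100
  prof <- 10 * (10 * s^3 - 15 * s^4 + 6 * s^5)
  r <- t(vapply(prof, function(a) rotvec_from_gaze(a, 0.6 * a), numeric(3)))
  traj <- minimum_jerk_trajectory(A = 10, D = 100)
  traj[, c("rx", "ry", "rz")] <- r
  rec <- structure(list(goal = r[101, ], start = r[1, ], end = r[101, ],
                        D = 100, amplitude = 11.7, controls = matrix(0, 6, 100),
                        trajectory = traj, endpoint_error_deg = 0),
                   class = "saccade_record")
  cc <- component_coupling(fake_dataset(list(rec)))
  expect_equal(cc$r, 1, tolerance = 1e-6)
  expect_true(cc$oblique)
})

test_that("direction-binned peak velocities aggregate correctly", {
  met <- data.frame(Phi = c(10, 20, 100, 110, 200),
                    R = c(5, 6, 5, 6, 15),
                    V_pk = c(100, 120, 200, 220, 300))
  tab <- direction_binned_vpk(met, dir_width = 30, amp_breaks = c(0, 10, 20))
  row_h <- tab[tab$dir_center == 15, ]
  expect_equal(row_h$n, 2)
  expect_equal(row_h$mean_vpk, 110)
  row_v <- tab[tab$dir_center == 105, ]
  expect_equal(row_v$mean_vpk, 210)
})
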