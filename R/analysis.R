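# coefficient of determination without summary.lm's perfect-fit warning
r_squared <- function(fit, intercept = TRUE) {
  y <- fitted(fit) + resid(fit)
  ss_tot <- if (intercept) sum((y - mean(y))^2) else sum(y^2)
  1 - sum(resid(fit)^2) / ss_tot
}

#' Kinematic metrics of one saccade
#'
#' Amplitude `R = sqrt(dAz^2 + dEl^2)` and direction
#' `Phi = atan2(dEl, dAz)` are computed from the on- and offset gaze angles
#' (deg; rightward = 0, upward = 90). The vectorial peak velocity is the
#' maximum angular speed `max ||omega||` in deg/s; component peak
#' velocities are taken from the gaze-angle derivatives. For
#' optimizer-produced saccades the movement interval is `[0, D]` with `D`
#' from the duration grid; for free traces (e.g. stimulation responses) an
#' onset/offset rule based on a 20 deg/s speed threshold with hysteresis is
#' applied.
#'
#' @param traj an `eye_trajectory`.
#' @param D duration in ms; `NULL` applies the threshold rule.
#' @param threshold onset/offset speed threshold (deg/s).
#' @return list of class `saccade_metrics`: `R`, `Phi`, `D`, `V_pk`,
#'   `V_pk_H`, `V_pk_V`, `onset`, `offset` (ms), `start`, `end` (gaze
#'   angles, deg).
#' @export
saccade_metrics <- function(traj, D = NULL, threshold = 20) {
  ang <- gaze_angles(as.matrix(traj[, c("rx", "ry", "rz")]))
  speed <- sqrt(traj$wx^2 + traj$wy^2 + traj$wz^2) * 180 / pi
  if (!is.null(D)) {
    onset <- 0L
    offset <- as.integer(D)
  } else {
    above <- which(speed > threshold)
    if (length(above) == 0)
      stop("no movement above the speed threshold", call. = FALSE)
    onset <- max(traj$t_ms[above[1]] - 1L, 0L)
    ipk <- which.max(speed)
    after <- which(speed < threshold & traj$t_ms > traj$t_ms[ipk])
    offset <- if (length(after)) traj$t_ms[after[1]] else traj$t_ms[nrow(traj)]
  }
  i0 <- match(onset, traj$t_ms); i1 <- match(offset, traj$t_ms)
  d_az <- unname(ang[i1, 1] - ang[i0, 1])
  d_el <- unname(ang[i1, 2] - ang[i0, 2])
  win <- i0:i1
  dt_s <- attr(traj, "dt")
  if (is.null(dt_s)) dt_s <- 1e-3
  vH <- diff(ang[, 1]) / dt_s
  vV <- diff(ang[, 2]) / dt_s
  winv <- win[-length(win)]
  structure(list(
    R = sqrt(d_az^2 + d_el^2),
    Phi = atan2(d_el, d_az) * 180 / pi,
    D = offset - onset,
    V_pk = max(speed[win]),
    V_pk_H = max(abs(vH[winv])),
    V_pk_V = max(abs(vV[winv])),
    onset = onset, offset = offset,
    start = ang[i0, ], end = ang[i1, ]), class = "saccade_metrics")
}

#' Tidy metrics table of a saccade data set
#'
#' One row per saccade: target and endpoint gaze angles, amplitude,
#' direction, duration, vectorial and component peak velocities.
#'
#' @param dataset a `saccade_dataset`.
#' @return data frame.
#' @export
dataset_metrics <- function(dataset) {
  rows <- lapply(dataset$records, function(rec) {
    m <- saccade_metrics(rec$trajectory, D = rec$D)
    tg <- gaze_angles(rec$goal)
    st <- gaze_angles(rec$start)
    data.frame(T_H = tg[1], T_V = tg[2],
               H_on = st[1], V_on = st[2],
               theta_H = m$end[1], phi_V = m$end[2],
               R = m$R, Phi = m$Phi, D = m$D,
               V_pk = m$V_pk, V_pk_H = m$V_pk_H, V_pk_V = m$V_pk_V,
               err_deg = rec$endpoint_error_deg)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stimulus-response accuracy regression
#'
#' Component-wise ordinary least squares of the final gaze angles on the
#' target angles, `azimuth = a + b T_H` and `elevation = c + d T_V`, with
#' coefficients of determination and the signed endpoint error
#' distributions.
#'
#' @param dataset a `saccade_dataset`, or a data frame with columns
#'   `theta_H`, `phi_V`, `T_H`, `T_V`.
#' @return list of class `accuracy_fit` with `a`, `b`, `c`, `d`,
#'   `r2_H`, `r2_V`, `err_mean`, `err_sd` (each length-2: H, V).
#' @export
accuracy_regression <- function(dataset) {
  d <- if (inherits(dataset, "saccade_dataset")) dataset_metrics(dataset)
       else dataset
  fh <- lm(theta_H ~ T_H, data = d)
  fv <- lm(phi_V ~ T_V, data = d)
  errH <- d$theta_H - d$T_H
  errV <- d$phi_V - d$T_V
  structure(list(a = unname(coef(fh)[1]), b = unname(coef(fh)[2]),
                 c = unname(coef(fv)[1]), d = unname(coef(fv)[2]),
                 r2_H = r_squared(fh), r2_V = r_squared(fv),
                 err_mean = c(H = mean(errH), V = mean(errV)),
                 err_sd = c(H = sd(errH), V = sd(errV)),
                 n = nrow(d)), class = "accuracy_fit")
}

#' @export
print.accuracy_fit <- function(x, ...) {
  cat(sprintf("<accuracy_fit> n=%d\n  azimuth  = %+.3f + %.3f T_H (r^2 = %.4f)\n",
              x$n, x$a, x$b, x$r2_H))
  cat(sprintf("  elevation= %+.3f + %.3f T_V (r^2 = %.4f)\n", x$c, x$d, x$r2_V))
  cat(sprintf("  errors: H %.2f +/- %.2f deg, V %.2f +/- %.2f deg\n",
              x$err_mean[1], x$err_sd[1], x$err_mean[2], x$err_sd[2]))
  invisible(x)
}

#' Main-sequence fit
#'
#' Two affine relations fitted by OLS over the saccade population:
#' `D = e + f R` (duration, ms) and `V_pk * D = k + m R` (both sides deg).
#' Together they predict a saturating amplitude-peak velocity relation, see
#' [predict_vpk()].
#'
#' @param metrics data frame from [dataset_metrics()] (or any frame with
#'   `R`, `D`, `V_pk`; `D` in ms).
#' @return list of class `main_sequence_fit` with `e` (ms), `f` (ms/deg),
#'   `k` (deg), `m` (dimensionless), the two r-squared values and the
#'   implied saturation velocity `m/f` in deg/s.
#' @export
main_sequence_fit <- function(metrics) {
  fD <- lm(D ~ R, data = metrics)
  VD <- metrics$V_pk * metrics$D / 1000   # deg
  fV <- lm(VD ~ R, data = metrics)
  e <- unname(coef(fD)[1]); f <- unname(coef(fD)[2])
  k <- unname(coef(fV)[1]); m <- unname(coef(fV)[2])
  structure(list(e = e, f = f, k = k, m = m,
                 r2_D = r_squared(fD), r2_VD = r_squared(fV),
                 saturation = 1000 * m / f), class = "main_sequence_fit")
}

#' Predicted peak velocity from the main-sequence fit
#'
#' Combining the two affine main-sequence relations (and dropping the small
#' offset `k`, so that the prediction vanishes at zero amplitude) gives
#' `V_pk(R) = (m/e) / (1/R + f/e)` with the duration coefficients in
#' seconds; the prediction saturates at `m/f` deg/s as `R` grows.
#'
#' @param R amplitude(s), deg.
#' @param fit a [main_sequence_fit()].
#' @return predicted peak velocity, deg/s.
#' @export
predict_vpk <- function(R, fit) {
  e_s <- fit$e / 1000; f_s <- fit$f / 1000
  (fit$m / e_s) / (1 / R + f_s / e_s)
}

#' @export
print.main_sequence_fit <- function(x, ...) {
  cat(sprintf("<main_sequence_fit> D = %.1f + %.2f R (r^2=%.3f); V*D = %.2f + %.3f R (r^2=%.3f)\n",
              x$e, x$f, x$r2_D, x$k, x$m, x$r2_VD))
  cat(sprintf("  saturation velocity m/f = %.0f deg/s\n", x$saturation))
  invisible(x)
}

#' Normalize a planar trajectory to the movement axis
#'
#' Translates a 2D (azimuth, elevation) trace to the origin and rotates it
#' by the overall movement direction so the displacement lies on the
#' positive horizontal axis. Used by the curvature index.
#'
#' @param trace n x 2 matrix of gaze angles (deg), columns azimuth,
#'   elevation.
#' @return n x 2 matrix of the rotated trace.
#' @export
normalize_trajectory <- function(trace) {
  trace <- as.matrix(trace)
  tr <- sweep(trace, 2, trace[1, ])
  phi <- atan2(tr[nrow(tr), 2], tr[nrow(tr), 1])
  cbind(cos(phi) * tr[, 1] + sin(phi) * tr[, 2],
        -sin(phi) * tr[, 1] + cos(phi) * tr[, 2])
}

#' Signed curvature index of a saccade trajectory
#'
#' After [normalize_trajectory()], the index is the signed maximum
#' perpendicular deviation of the trace, normalized by the movement
#' amplitude: `C = -sign(dH_rot) * dev_max / |dH_rot|`, where `dev_max` is
#' the (signed) deviation of largest magnitude. Clockwise curvature is
#' positive; a rightward semicircle with its arc in the upper half plane
#' gives `C = -0.5`. Trajectories are classified `straight` for |C| < 0.03
#' and `curved` for |C| > 0.15, `intermediate` in between.
#'
#' @param trace n x 2 matrix of gaze angles (deg), or an `eye_trajectory`
#'   (its gaze-angle projection is used).
#' @return list of class `curvature_result` with `C` and `class`.
#' @export
curvature <- function(trace) {
  if (inherits(trace, "eye_trajectory"))
    trace <- gaze_angles(as.matrix(trace[, c("rx", "ry", "rz")]))
  rot <- normalize_trajectory(trace)
  run <- rot[nrow(rot), 1]
  if (abs(run) < 1e-9)
    stop("degenerate trajectory: zero displacement", call. = FALSE)
  dev <- rot[which.max(abs(rot[, 2])), 2]
  C <- -sign(run) * dev / abs(run)
  cls <- if (abs(C) < 0.03) "straight" else if (abs(C) > 0.15) "curved"
         else "intermediate"
  structure(list(C = C, class = cls), class = "curvature_result")
}

#' Listing-plane fit
#'
#' Least-squares plane through the origin fitted to instantaneous 3D eye
#' orientations: `r_x = alpha r_y + beta r_z` (ordinary LS of the torsional
#' on the other two components, matching the regression form of the plane
#' definition). The residual standard deviation is the plane "width",
#' reported in rad/2 and as the angular equivalent `2 atan(sigma)` in deg;
#' the tilt about the vertical axis is `atan(alpha)` in deg (a negative
#' tilt means the plane is rotated leftward, i.e. the primary position lies
#' to the right of straight ahead).
#'
#' @param r n x 3 matrix of rotation vectors (rad/2), or a
#'   `saccade_dataset` whose pooled trajectory samples are used.
#' @return list of class `listing_fit` with `alpha`, `beta`, `sigma`
#'   (rad/2), `sigma_deg`, `tilt_deg`, Pearson `r` of fitted vs observed
#'   torsion, and `n`.
#' @export
fit_listing_plane <- function(r) {
  if (inherits(r, "saccade_dataset"))
    r <- do.call(rbind, lapply(r$records, function(rec)
      as.matrix(rec$trajectory[, c("rx", "ry", "rz")])))
  r <- as.matrix(r)
  stopifnot(ncol(r) == 3)
  fit <- lm.fit(r[, 2:3, drop = FALSE], r[, 1])
  alpha <- unname(fit$coefficients[1]); beta <- unname(fit$coefficients[2])
  res <- fit$residuals
  sigma <- sqrt(mean(res^2))
  pred <- r[, 1] - res
  rr <- if (sd(pred) < 1e-15 || sd(r[, 1]) < 1e-15) NA_real_
        else cor(pred, r[, 1])
  structure(list(alpha = alpha, beta = beta, sigma = sigma,
                 sigma_deg = 2 * atan(sigma) * 180 / pi,
                 tilt_deg = atan(alpha) * 180 / pi,
                 r = rr, n = nrow(r)), class = "listing_fit")
}

#' @export
print.listing_fit <- function(x, ...) {
  cat(sprintf("<listing_fit> r_x = %+.4f r_y %+.4f r_z  (n=%d, r=%.3f)\n",
              x$alpha, x$beta, x$n, x$r))
  cat(sprintf("  width sigma = %.5f rad/2 (%.3f deg), tilt %.2f deg about z\n",
              x$sigma, x$sigma_deg, x$tilt_deg))
  invisible(x)
}

#' Position-dependent peak-velocity regression
#'
#' Nested OLS on z-scored variables for horizontal saccades: the peak
#' velocity is regressed first on amplitude alone,
#' `V_pk_hat = g_R1 * dH_hat`, then on amplitude plus initial orientation,
#' `V_pk_hat = g_R2 * dH_hat + g_Hon * H_on_hat`. The initial-orientation
#' regressor is signed against the movement direction (positive =
#' contralateral start), so a positive `g_Hon` means saccades are faster
#' when launched from the side opposite to their direction. Saccades below
#' the amplitude cut are excluded. The added regressor is assessed by the
#' nested-model F test.
#'
#' @param metrics data frame with columns `V_pk`, `R`, `H_on` and `Phi`
#'   (only near-horizontal movements should be included), or a
#'   `saccade_dataset`.
#' @param min_amplitude amplitude inclusion threshold (deg).
#' @return list of class `position_gain_fit` with `g_R1`, `g_R2`, `g_Hon`,
#'   `r2_1`, `r2_2`, `p_added` (F-test p of the added regressor), `n`, and
#'   the z-score normalizers.
#' @export
position_gain_regression <- function(metrics, min_amplitude = 6) {
  if (inherits(metrics, "saccade_dataset")) metrics <- dataset_metrics(metrics)
  d <- metrics[metrics$R >= min_amplitude, , drop = FALSE]
  if (nrow(d) < 4)
    stop("too few saccades above the amplitude threshold", call. = FALSE)
  dir_sign <- sign(cos(d$Phi * pi / 180))   # +1 rightward, -1 leftward
  h_rel <- -dir_sign * d$H_on
  zs <- function(z) {
    s <- sd(z)
    if (s < 1e-12) stop("zero-variance regressor", call. = FALSE)
    (z - mean(z)) / s
  }
  v <- zs(d$V_pk); a <- zs(d$R); h <- zs(h_rel)
  f1 <- lm(v ~ a - 1)
  f2 <- lm(v ~ a + h - 1)
  pf <- anova(f1, f2)[["Pr(>F)"]][2]
  structure(list(g_R1 = unname(coef(f1)[1]), g_R2 = unname(coef(f2)[1]),
                 g_Hon = unname(coef(f2)[2]),
                 r2_1 = r_squared(f1, intercept = FALSE),
                 r2_2 = r_squared(f2, intercept = FALSE),
                 p_added = pf, n = nrow(d),
                 normalizers = list(V_pk = c(mean(d$V_pk), sd(d$V_pk)),
                                    R = c(mean(d$R), sd(d$R)),
                                    H_on = c(mean(h_rel), sd(h_rel)))),
            class = "position_gain_fit")
}

#' @export
print.position_gain_fit <- function(x, ...) {
  cat(sprintf("<position_gain_fit> n=%d: g_R=%.3f (r^2=%.3f) -> g_R=%.3f, g_Hon=%.3f (r^2=%.3f), p=%.2g\n",
              x$n, x$g_R1, x$r2_1, x$g_R2, x$g_Hon, x$r2_2, x$p_added))
  invisible(x)
}

#' Component cross-coupling of oblique saccades
#'
#' Within-saccade Pearson correlation between the horizontal and vertical
#' gaze-velocity profiles, split into oblique saccades (direction at least
#' `oblique_margin` deg away from all cardinal directions) and cardinal
#' ones. Under a common vectorial velocity source the two components are
#' scaled versions of each other and correlate near +1 for oblique
#' movements.
#'
#' @param dataset a `saccade_dataset`.
#' @param oblique_margin degrees from the cardinal axes defining "oblique".
#' @return list of class `coupling_result` with per-saccade correlations
#'   `r`, logical `oblique`, and summary means/sds per group.
#' @export
component_coupling <- function(dataset, oblique_margin = 20) {
  met <- dataset_metrics(dataset)
  rs <- vapply(seq_along(dataset$records), function(j) {
    tr <- dataset$records[[j]]$trajectory
    ang <- gaze_angles(as.matrix(tr[, c("rx", "ry", "rz")]))
    i1 <- dataset$records[[j]]$D + 1L
    # sign-align the components with the movement quadrant so that perfectly
    # coupled (scaled) profiles give r = +1 in every direction
    sH <- sign(cos(met$Phi[j] * pi / 180)); if (sH == 0) sH <- 1
    sV <- sign(sin(met$Phi[j] * pi / 180)); if (sV == 0) sV <- 1
    vh <- sH * diff(ang[1:i1, 1]); vv <- sV * diff(ang[1:i1, 2])
    suppressWarnings(cor(vh, vv))
  }, 0)
  dphi <- abs(((met$Phi %% 90) + 45) %% 90 - 45)   # distance to nearest cardinal
  obl <- dphi >= oblique_margin
  structure(list(r = rs, oblique = obl,
                 mean_oblique = mean(rs[obl]), sd_oblique = sd(rs[obl]),
                 mean_cardinal = mean(rs[!obl]), sd_cardinal = sd(rs[!obl])),
            class = "coupling_result")
}

#' Common-source prediction of component peak velocity
#'
#' Under the common-source model the component peak velocity follows the
#' vectorial main sequence scaled by the direction cosine (horizontal) or
#' sine (vertical): e.g. `V_pk(dH, Phi) = (m/e) cos(Phi) / (1/dH + f/e)`.
#' The prediction reuses the global [main_sequence_fit()] and has no free
#' parameters of its own; at `Phi = 0` the horizontal prediction reduces
#' exactly to the vectorial [predict_vpk()].
#'
#' @param delta component amplitude (deg), `dH` or `dV`.
#' @param Phi saccade vector direction (deg).
#' @param fit a [main_sequence_fit()].
#' @param component `"H"` or `"V"`.
#' @return predicted component peak velocity, deg/s.
#' @export
common_source_prediction <- function(delta, Phi, fit, component = c("H", "V")) {
  component <- match.arg(component)
  e_s <- fit$e / 1000; f_s <- fit$f / 1000
  scale <- if (component == "H") cos(Phi * pi / 180) else sin(Phi * pi / 180)
  (fit$m / e_s) * scale / (1 / delta + f_s / e_s)
}

#' Within-saccade muscle-pair correlations
#'
#' Pearson correlation between the command signals of named muscle pairs
#' during each saccade. Antagonist pairs (LR-MR, SR-IR, SO-IO) are expected
#' near -1, agonist pairs (SR-IO, SO-IR) near +1 for movements that engage
#' them.
#'
#' @param dataset a `saccade_dataset`.
#' @param pairs character matrix-like list of 2-vectors naming the pairs.
#' @return list of class `synergy_result`: data frame `r` (one column per
#'   pair, one row per saccade) plus the per-saccade direction `Phi`.
#' @export
synergy_correlations <- function(dataset,
                                 pairs = list(c("LR", "MR"), c("SR", "IR"),
                                              c("SO", "IO"), c("SR", "IO"),
                                              c("SO", "IR"))) {
  met <- dataset_metrics(dataset)
  tab <- sapply(pairs, function(pr) {
    vapply(dataset$records, function(rec) {
      u <- rec$controls
      suppressWarnings(cor(u[pr[1], ], u[pr[2], ]))
    }, 0)
  })
  colnames(tab) <- vapply(pairs, paste, "", collapse = "-")
  structure(list(r = as.data.frame(tab), Phi = met$Phi),
            class = "synergy_result")
}

#' Direction-binned peak velocities
#'
#' Mean and sd of the vectorial peak velocity in direction bins, separately
#' per amplitude bin -- the population view of the direction dependence of
#' saccade speed.
#'
#' @param metrics data frame from [dataset_metrics()] or a
#'   `saccade_dataset`.
#' @param dir_width direction bin width (deg).
#' @param amp_breaks amplitude bin edges (deg).
#' @return data frame with `amp_bin`, `dir_center`, `n`, `mean_vpk`,
#'   `sd_vpk`.
#' @export
direction_binned_vpk <- function(metrics, dir_width = 30,
                                 amp_breaks = c(0, 10, 20, 30, 50)) {
  if (inherits(metrics, "saccade_dataset")) metrics <- dataset_metrics(metrics)
  phi <- metrics$Phi %% 360
  dbin <- floor(phi / dir_width)
  abin <- cut(metrics$R, amp_breaks, include.lowest = TRUE)
  agg <- aggregate(metrics$V_pk,
                   by = list(amp_bin = abin, dir_bin = dbin),
                   FUN = function(v) c(n = length(v), m = mean(v), s = sd(v)))
  data.frame(amp_bin = agg$amp_bin,
             dir_center = (agg$dir_bin + 0.5) * dir_width,
             n = agg$x[, "n"], mean_vpk = agg$x[, "m"], sd_vpk = agg$x[, "s"])
}
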