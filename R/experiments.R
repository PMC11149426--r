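#' Saccade paradigm configuration
#'
#' Three data-generating paradigms sample the oculomotor range:
#' `zero_initial` (every saccade starts at the reference fixation, random 2D
#' goals), `continuous` (each saccade starts where the previous one ended),
#' and `horizontal_continuous` (targets drawn on the horizontal meridian
#' from a discrete grid). Goals are drawn in `[-range, +range]` rad/2 with
#' zero target torsion. Desk-scale sizes (30/50/30) keep a full run in
#' minutes; `full = TRUE` switches to the campaign sizes 199/298/202.
#'
#' @param name paradigm name.
#' @param n number of saccades; defaults per paradigm (desk scale).
#' @param range half-width of the goal range (rad/2), within [0, 0.3].
#' @param grid_step horizontal-paradigm target grid spacing (rad/2).
#' @param seed integer seed.
#' @param full use the full campaign sizes instead of desk scale.
#' @return list of class `paradigm_config`.
#' @export
paradigm_config <- function(name = c("zero_initial", "continuous",
                                     "horizontal_continuous"),
                            n = NULL, range = 0.3, grid_step = 0.012,
                            seed = 1, full = FALSE) {
  name <- match.arg(name)
  stopifnot(range > 0, range <= 0.3, grid_step > 0)
  if (is.null(n)) {
    n <- if (full) switch(name, zero_initial = 199L, continuous = 298L,
                          horizontal_continuous = 202L)
         else switch(name, zero_initial = 30L, continuous = 50L,
                     horizontal_continuous = 30L)
  }
  structure(list(name = name, n = as.integer(n), range = range,
                 grid_step = grid_step, seed = as.integer(seed)),
            class = "paradigm_config")
}

new_saccade_record <- function(sac, goal, x0, seed = NA_integer_) {
  traj <- sac$trajectory
  iD <- sac$D_opt + 1L
  end <- c(traj$rx[iD], traj$ry[iD], traj$rz[iD])
  disp <- rot_between(x0$r, goal$r)
  structure(list(
    goal = goal$r, start = x0$r, end = end,
    D = sac$D_opt,
    amplitude = rot_angle(disp),
    displacement = disp,
    controls = sac$controls,
    u_start = sac$u_start,
    trajectory = traj,
    cost = sac$cost,
    cost_profile = sac$cost_profile,
    endpoint_error_deg = sac$endpoint_error_deg,
    seed = seed), class = "saccade_record")
}

run_paradigm_core <- function(plant, cfg, weights, targets, starts_chained,
                              ...) {
  records <- vector("list", nrow(targets))
  x0 <- eye_state()
  for (k in seq_len(nrow(targets))) {
    goal <- saccade_goal(targets[k, 1], targets[k, 2])
    sac <- optimal_saccade(plant, goal, x0, weights, ...)
    records[[k]] <- new_saccade_record(sac, goal, x0, cfg$seed)
    if (starts_chained) {
      x0 <- eye_state(records[[k]]$end, c(0, 0, 0))
    }
  }
  structure(list(records = records, paradigm = cfg$name, config = cfg,
                 n = length(records)),
            class = "saccade_dataset")
}

#' @export
print.saccade_dataset <- function(x, ...) {
  amp <- vapply(x$records, `[[`, 0, "amplitude")
  cat(sprintf("<saccade_dataset> %s paradigm, %d saccades, amplitudes %.1f-%.1f deg\n",
              x$paradigm, x$n, min(amp), max(amp)))
  invisible(x)
}

#' Run the zero-initial paradigm
#'
#' Every saccade starts at the reference fixation `(0,0,0)`; 2D goals are
#' drawn uniformly at random in the configured range with zero target
#' torsion. Seeded and reproducible.
#'
#' @param plant an [eye_plant()].
#' @param cfg a [paradigm_config()] (name `zero_initial`).
#' @param weights a [cost_weights()].
#' @param ... further arguments to [optimal_saccade()].
#' @return a `saccade_dataset`.
#' @export
run_zero_initial <- function(plant, cfg = paradigm_config("zero_initial"),
                             weights = cost_weights(), ...) {
  set.seed(cfg$seed)
  targets <- cbind(gy = runif(cfg$n, -cfg$range, cfg$range),
                   gz = runif(cfg$n, -cfg$range, cfg$range))
  run_paradigm_core(plant, cfg, weights, targets, starts_chained = FALSE, ...)
}

#' Run the continuous paradigm
#'
#' Goals are drawn as in the zero-initial paradigm, but each saccade starts
#' at the realized endpoint of the previous one, so initial orientations
#' cover the oculomotor range and amplitudes extend beyond the goal range
#' (up to about 50 deg).
#'
#' @inheritParams run_zero_initial
#' @export
run_continuous <- function(plant, cfg = paradigm_config("continuous"),
                           weights = cost_weights(), ...) {
  set.seed(cfg$seed)
  targets <- cbind(gy = runif(cfg$n, -cfg$range, cfg$range),
                   gz = runif(cfg$n, -cfg$range, cfg$range))
  run_paradigm_core(plant, cfg, weights, targets, starts_chained = TRUE, ...)
}

#' Run the horizontal continuous paradigm
#'
#' Purely horizontal chained saccades: targets are drawn at random from the
#' discrete grid `seq(-range, range, by = grid_step)` on the horizontal
#' meridian, with vertical and torsional goal components kept at zero.
#'
#' @inheritParams run_zero_initial
#' @export
run_horizontal_continuous <- function(plant,
                                      cfg = paradigm_config("horizontal_continuous"),
                                      weights = cost_weights(), ...) {
  set.seed(cfg$seed)
  gridv <- seq(-cfg$range, cfg$range, by = cfg$grid_step)
  targets <- cbind(gy = 0, gz = sample(gridv, cfg$n, replace = TRUE))
  run_paradigm_core(plant, cfg, weights, targets, starts_chained = TRUE, ...)
}

#' Muscle stimulation configuration
#'
#' Mimics electrical micro-stimulation of a single muscle's motor nerve: a
#' Gaussian command pulse superposed on the holding command of one muscle
#' while the eye fixates at a set of initial orientations.
#'
#' @param muscle stimulated muscle, one of `"LR"`, `"MR"`, `"SO"`.
#' @param width_ms full width at half maximum of the Gaussian pulse (ms).
#' @param amplitude pulse amplitude (mm of commanded shortening); `NULL`
#'   defaults to the peak agonist drive of a 10 deg optimal saccade,
#'   computed on the fly.
#' @param onsets initial orientations: for LR/MR a vector of vertical
#'   eccentricities (deg, upward positive); for SO a vector of horizontal
#'   eccentricities (deg, rightward positive). Default 13 values spanning
#'   +/- 12 deg.
#' @param horizon_ms simulated horizon per trial (ms).
#' @param onset_ms pulse centre time (ms).
#' @return list of class `stimulation_config`.
#' @export
stimulation_config <- function(muscle = c("LR", "MR", "SO"), width_ms = 21,
                               amplitude = NULL,
                               onsets = seq(-12, 12, length.out = 13),
                               horizon_ms = 250, onset_ms = 40) {
  muscle <- match.arg(muscle)
  structure(list(muscle = muscle, width_ms = width_ms, amplitude = amplitude,
                 onsets = onsets, horizon_ms = horizon_ms,
                 onset_ms = onset_ms), class = "stimulation_config")
}

default_pulse_amplitude <- function(plant, weights = cost_weights()) {
  s <- optimal_saccade(plant, saccade_goal(0, -tan(5 * pi / 180)))
  max(abs(sweep(s$controls, 1, s$u_start)))
}

#' Simulated muscle-stimulation experiment
#'
#' For each initial orientation the eye is held at fixation by the static
#' holding command, a Gaussian pulse (FWHM `width_ms`) is superposed on the
#' stimulated muscle's command, and the plant is integrated. The torsional
#' displacement accumulated over the stimulation-driven response,
#' `Delta r_x = integral of dr_x/dt` from pulse onset to the turning point
#' of the evoked movement (maximum gaze displacement; the subsequent passive
#' elastic return is not part of the response), is regressed on the initial
#' eccentricity. A plant that implemented Listing's law mechanically would
#' show no such orientation-dependent torsion.
#'
#' @param plant an [eye_plant()].
#' @param cfg a [stimulation_config()].
#' @return list of class `stimulation_result`: per-trial table (`onset_deg`,
#'   `r_on` component, `delta_rx`, `gaze_shift_deg`), the fitted slope,
#'   intercept and `r.squared` of `delta_rx` on the relevant onset
#'   component, and the trial trajectories.
#' @export
stimulate_muscle <- function(plant, cfg = stimulation_config()) {
  m <- match(cfg$muscle, plant$geometry$muscles)
  amp <- cfg$amplitude
  if (is.null(amp)) amp <- default_pulse_amplitude(plant)
  sig <- cfg$width_ms / (2 * sqrt(2 * log(2)))
  n <- cfg$horizon_ms
  tt <- seq_len(n)
  pulse <- amp * exp(-(tt - cfg$onset_ms)^2 / (2 * sig^2))
  trials <- vector("list", length(cfg$onsets))
  tab <- data.frame(onset_deg = cfg$onsets, r_on = NA_real_,
                    delta_rx = NA_real_, gaze_shift_deg = NA_real_)
  for (j in seq_along(cfg$onsets)) {
    e <- cfg$onsets[j]
    r_on <- if (cfg$muscle == "SO") rotvec_from_gaze(e, 0)
            else rotvec_from_gaze(0, e)
    uf <- fixation_command(plant, r_on)
    ctr <- matrix(uf, 6, n)
    ctr[m, ] <- ctr[m, ] + pulse
    tr <- simulate_plant(plant, ctr, eye_state(r_on))
    disp <- sqrt((tr$ry - tr$ry[1])^2 + (tr$rz - tr$rz[1])^2)
    it <- which.max(disp)
    tab$r_on[j] <- if (cfg$muscle == "SO") r_on[3] else r_on[2]
    tab$delta_rx[j] <- tr$rx[it] - tr$rx[1]
    tab$gaze_shift_deg[j] <- 2 * atan(disp[it]) * 180 / pi
    trials[[j]] <- tr
  }
  fit <- lm(delta_rx ~ r_on, data = tab)
  structure(list(muscle = cfg$muscle, table = tab,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r.squared = summary(fit)$r.squared,
                 amplitude = amp, config = cfg, trials = trials),
            class = "stimulation_result")
}

#' @export
print.stimulation_result <- function(x, ...) {
  cat(sprintf("<stimulation_result> %s pulse (%.2f mm, FWHM %g ms), %d onsets\n",
              x$muscle, x$amplitude, x$config$width_ms, nrow(x$table)))
  cat(sprintf("  delta_rx = %.4g * r_on %+.2g   (r^2 = %.4f)\n",
              x$slope, x$intercept, x$r.squared))
  invisible(x)
}

#' @rdname stimulate_muscle
#' @details `stimulate_so()` is the trochlear variant: the SO muscle is
#'   pulsed from initial orientations along the horizontal meridian and the
#'   accumulated cyclo-torsion is regressed on the initial horizontal
#'   component.
#' @export
stimulate_so <- function(plant, cfg = stimulation_config("SO")) {
  cfg$muscle <- "SO"
  stimulate_muscle(plant, cfg)
}
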