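#' Extra-ocular muscle geometry
#'
#' Describes the six tendons of the biomimetic right eye in a head-fixed
#' frame with x pointing forward along the reference gaze line, y leftward
#' and z upward (all mm, globe centred at the origin). Each tendon runs as a
#' straight cable from its insertion on the globe surface to a fixed
#' anchoring point: the orbital origin for the four recti (a common annulus
#' displaced nasally, i.e. leftward for a right eye), or a pulley point for
#' the two obliques (the trochlea for SO, an orbital-floor pulley for IO).
#' Cable paths do not wrap around the globe and there is no side-slip
#' constraint; the pulling direction at any eye orientation is the straight
#' segment from the rotated insertion to the anchor.
#'
#' The default coordinates are digitized from standard human-eye geometry
#' (rectus insertions 5.5-7.7 mm behind the limbus, common tendinous ring
#' about 35 mm behind the globe centre and displaced nasally, oblique
#' pulleys at the anterior nasal orbit) and scaled to a 12 mm globe. They
#' are a calibrated stand-in for the physical prototype, shipped as an
#' editable structure.
#'
#' @param radius globe radius in mm.
#' @param insertion 6 x 3 matrix of unit vectors: insertion directions on the
#'   globe (rows LR, MR, SR, IR, SO, IO). Rows are re-normalized.
#' @param attach 6 x 3 matrix of anchor points in the head frame (mm):
#'   orbital origins for the recti, pulley points for SO and IO.
#' @param pulley logical length 6; which anchors are pulleys.
#' @param gain spindle gain, mm of cable per unit motor command (kept at 1 so
#'   commands are expressed directly as commanded cable shortening in mm).
#' @return an object of class `eye_geometry`.
#' @export
eye_geometry <- function(radius = 12,
                         insertion = NULL,
                         attach = NULL,
                         pulley = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
                         gain = rep(1, 6)) {
  muscles <- c("LR", "MR", "SR", "IR", "SO", "IO")
  if (is.null(insertion)) {
    insertion <- rbind(
      LR = c(cos(75 * pi / 180), -sin(75 * pi / 180), 0),
      MR = c(cos(70 * pi / 180),  sin(70 * pi / 180), 0),
      SR = c(cos(45 * pi / 180),  0.05,  sin(45 * pi / 180)),
      IR = c(cos(43 * pi / 180),  0.05, -sin(43 * pi / 180)),
      SO = c(-0.42, -0.42,  0.80),
      IO = c(-0.42, -0.52, -0.74))
  }
  if (is.null(attach)) {
    attach <- rbind(
      LR = c(-35, 2.0,  0.0),
      MR = c(-35, 4.0,  0.0),
      SR = c(-35, 3.0,  1.5),
      IR = c(-35, 3.0, -1.5),
      SO = c(5, 10,  11),
      IO = c(6, 10, -11))
  }
  insertion <- as.matrix(insertion)
  attach <- as.matrix(attach)
  stopifnot(nrow(insertion) == 6, ncol(insertion) == 3,
            nrow(attach) == 6, ncol(attach) == 3,
            length(pulley) == 6, length(gain) == 6, radius > 0)
  insertion <- insertion / sqrt(rowSums(insertion^2))
  rownames(insertion) <- rownames(attach) <- muscles
  structure(list(muscles = muscles, radius = radius,
                 insertion = insertion, attach = attach,
                 pulley = as.logical(pulley), gain = as.numeric(gain)),
            class = "eye_geometry")
}

#' Physical parameters of the eye plant
#'
#' The eye globe is a rigid body rotating about its fixed centre under the
#' net tendon torque, a single viscous damping term (standing in for the
#' sliding supports of the physical prototype; Coulomb friction is omitted)
#' and its own gyroscopic term. The default values are a calibration chosen
#' so that optimal saccades land on a human-like main sequence (peak
#' velocities of a few hundred deg/s for 10-25 deg movements) and so that
#' step responses are overdamped; they are documented as calibration, not as
#' measured prototype constants.
#'
#' @param inertia length-3 diagonal of the eye-frame inertia tensor
#'   (kg mm^2). Mildly anisotropic by default (camera payload) so that the
#'   head-frame inertia depends on eye orientation; pass equal entries for an
#'   isotropic globe.
#' @param damping viscous damping coefficient (N mm s/rad).
#' @param stiffness tendon spring constant k (N/mm), common to all tendons.
#' @param pretension baseline tendon tension at the straight-ahead fixation (N).
#' @param dt integration step (s); the plant is sampled at 1 ms.
#' @param tension_floor minimum admissible static tension (N) when solving
#'   fixation commands, guarding against slack.
#' @return an object of class `plant_params`.
#' @export
plant_params <- function(inertia = c(0.48, 0.42, 0.45),
                         damping = 0.8,
                         stiffness = 0.25,
                         pretension = 0.6,
                         dt = 1e-3,
                         tension_floor = 0.02) {
  stopifnot(length(inertia) == 3, all(inertia > 0), damping > 0,
            stiffness > 0, pretension > 0, dt > 0, tension_floor >= 0)
  structure(list(inertia = as.numeric(inertia), damping = damping,
                 stiffness = stiffness, pretension = pretension,
                 dt = dt, tension_floor = tension_floor),
            class = "plant_params")
}

#' @export
print.eye_geometry <- function(x, ...) {
  cat("<eye_geometry> right eye, globe radius", x$radius, "mm\n")
  cat("  muscles:", paste(x$muscles, collapse = " "),
      "(pulley-routed:", paste(x$muscles[x$pulley], collapse = " "), ")\n")
  invisible(x)
}

#' @export
print.plant_params <- function(x, ...) {
  cat("<plant_params> inertia diag", paste(signif(x$inertia, 3), collapse = "/"),
      "kg mm^2, damping", x$damping, "N mm s/rad\n")
  cat("  stiffness", x$stiffness, "N/mm, pretension", x$pretension,
      "N, dt", x$dt * 1000, "ms\n")
  invisible(x)
}
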