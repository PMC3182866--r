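#' Object specification
#'
#' The manipulated object is idealized as a point mass `m` at the end of a
#' rigid massless rod of length `r` grasped at its base.
#'
#' @param mass_kg Point mass in kilograms (> 0).
#' @param rod_length_m Rod length in meters (> 0); the experimental object
#'   had an 8 cm rod.
#' @return An object of class `object_spec`.
#' @examples
#' object_spec(mass_kg = 0.7)
#' @export
object_spec <- function(mass_kg, rod_length_m = 0.08) {
  if (mass_kg <= 0 || rod_length_m <= 0) abort("mass and rod length must be > 0")
  structure(list(mass_kg = mass_kg, rod_length_m = rod_length_m),
            class = "object_spec")
}

#' Minimum-jerk rotation profile
#'
#' Rest-to-rest fifth-order polynomial angle profile covering `amplitude_deg`
#' in `duration_s`. The within-trial kinematics of the rotation are not
#' constrained by the trial-level models; a smooth, repeatable rest-to-rest
#' profile is needed only to define the peak object force used to normalize
#' adaptation measurements, and minimum jerk is the standard choice for
#' point-to-point human movement. Peak angular speed of the profile is
#' `15/8 * amplitude / duration`.
#'
#' @param amplitude_deg Signed rotation amplitude in degrees (CW negative by
#'   the package convention); must be nonzero.
#' @param duration_s Movement duration in seconds (> 0). The task required
#'   movements within 0.4 s, the default.
#' @param n_samples Number of uniform time samples (>= 3).
#' @param start_angle_deg Rod angle at movement start, degrees.
#' @return A tibble of class `rotation_profile` with columns `time` (s),
#'   `angle` (deg), `angular_velocity` (deg/s), `angular_acceleration`
#'   (deg/s^2).
#' @examples
#' prof <- minimum_jerk_profile(40, 0.4, 401, start_angle_deg = -20)
#' max(prof$angular_velocity)  # 187.5 deg/s
#' @export
minimum_jerk_profile <- function(amplitude_deg, duration_s = 0.4,
                                 n_samples = 401L, start_angle_deg = 0) {
  if (amplitude_deg == 0) abort("amplitude must be nonzero")
  if (duration_s <= 0) abort("duration must be > 0")
  if (n_samples < 3) abort("need at least 3 samples")
  t <- seq(0, duration_s, length.out = n_samples)
  s <- t / duration_s
  shape <- 10 * s^3 - 15 * s^4 + 6 * s^5
  dshape <- (30 * s^2 - 60 * s^3 + 30 * s^4) / duration_s
  ddshape <- (60 * s - 180 * s^2 + 120 * s^3) / duration_s^2
  tibble::new_tibble(
    tibble::tibble(
      time = t,
      angle = start_angle_deg + amplitude_deg * shape,
      angular_velocity = amplitude_deg * dshape,
      angular_acceleration = amplitude_deg * ddshape
    ),
    class = "rotation_profile"
  )
}

#' Rigid-body loads of the rotated object
#'
#' Computes the torque and planar handle force generated by the object for a
#' rotation profile. With angles converted to radians, the torque is
#' `tau = m r^2 thetadd`, the tangential force (perpendicular to the rod, in
#' the direction of tangential acceleration) is `Ft = m r thetadd`, and the
#' centripetal force (parallel to the rod, toward the rotation center) is
#' `Fc = m r thetad^2`. The force in the fixed manipulandum frame is obtained
#' by rotating the rod-frame force through the rod angle with a clockwise
#' rotation matrix (rod angle 0 = +y axis, positive angles counter-clockwise).
#'
#' @param profile A [minimum_jerk_profile()] tibble (or any tibble with the
#'   same columns).
#' @param object An [object_spec()].
#' @return A tibble of class `load_trace` with columns `time`, `angle`,
#'   `torque` (N m), `tangential_force`, `centripetal_force`, `force_x`,
#'   `force_y` (N).
#' @examples
#' obj <- object_spec(0.8)
#' loads <- object_loads(minimum_jerk_profile(40), obj)
#' max(sqrt(loads$force_x^2 + loads$force_y^2))
#' @export
object_loads <- function(profile, object) {
  stopifnot(inherits(object, "object_spec"))
  deg2rad <- pi / 180
  m <- object$mass_kg
  r <- object$rod_length_m
  thetad <- profile$angular_velocity * deg2rad
  thetadd <- profile$angular_acceleration * deg2rad
  torque <- m * r^2 * thetadd
  ft <- m * r * thetadd
  fc <- m * r * thetad^2
  # rod frame: x along tangential direction, y along the rod toward center;
  # rotate by the rod angle (clockwise matrix applied to the rod-frame force)
  theta <- profile$angle * deg2rad
  fx <- ft * cos(theta) + fc * sin(theta)
  fy <- -ft * sin(theta) + fc * cos(theta)
  tibble::new_tibble(
    tibble::tibble(time = profile$time, angle = profile$angle, torque = torque,
                   tangential_force = ft, centripetal_force = fc,
                   force_x = fx, force_y = fy),
    class = "load_trace"
  )
}

#' Peak force generated by the object over a rotation
#'
#' Maximum over time of the magnitude of the planar handle force. This is the
#' denominator of the adaptation ratio: on error-clamp trials the subject's
#' peak force is divided by the peak force the object would have generated.
#'
#' @inheritParams object_loads
#' @return Peak force in newtons (scalar).
#' @examples
#' peak_object_force(object_spec(0.7))
#' @export
peak_object_force <- function(object, profile = minimum_jerk_profile(40)) {
  loads <- object_loads(profile, object)
  max(sqrt(loads$force_x^2 + loads$force_y^2))
}
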