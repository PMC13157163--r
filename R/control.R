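#' Control parameters
#'
#' All constants of the motor control, sensing and trial loop.
#'
#' @param tau1 Synaptic time constant for the speed/heading-to-velocity
#'   conjunction, seconds (default 0.02).
#' @param tau2 Synaptic time constant for the position integrator and the
#'   error-based trajectory update, seconds (default 0.1).
#' @param v_max Maximal speed, m/s (default 0.5).
#' @param eps Minimum safety distance epsilon, metres (default 0.03).
#' @param D Critical distance to start slowing down, metres (default 0.4).
#' @param d_c Deceleration (re-acceleration) coefficient, m/s^2 (default 3).
#' @param alpha Steering smoothing: weight of the new steering angle
#'   (default 0.9; 10 percent of the previous angle is retained).
#' @param r_vis Target visibility radius, metres (default 0.3).
#' @param depth_threshold Depth band for the hydrostatic-pressure regime
#'   switch, metres (default 0.2).
#' @param n_bvc Number of BVC angular bins (default 24, i.e. 15 degrees).
#' @param bvc_range Maximal BVC receptive field, metres (default 1.4).
#' @param t_max Maximal simulation time, seconds (default 45).
#' @param v_eps Small speed boost added before the slow-down scaling so the
#'   agent can recover from a full stop, m/s (default 0.05).
#' @param noise_sigma Gaussian noise scale injected into the positional
#'   state, metres per sqrt(second) (default 0).
#' @param dt Simulation step, seconds (default 0.001).
#' @param capture_radius Trial ends when the agent is within this distance
#'   of the target, metres (default 0.05).
#' @return An object of class `control_params`.
#' @export
control_params <- function(tau1 = 0.02, tau2 = 0.1, v_max = 0.5,
                           eps = 0.03, D = 0.4, d_c = 3, alpha = 0.9,
                           r_vis = 0.3, depth_threshold = 0.2,
                           n_bvc = 24, bvc_range = 1.4, t_max = 45,
                           v_eps = 0.05, noise_sigma = 0, dt = 0.001,
                           capture_radius = 0.05) {
  stopifnot(eps > 0, eps < D, alpha >= 0, alpha <= 1, v_max > 0,
            tau1 > 0, tau2 > 0, n_bvc >= 1, dt > 0, t_max > 0)
  structure(list(tau1 = tau1, tau2 = tau2, v_max = v_max, eps = eps,
                 D = D, d_c = d_c, alpha = alpha, r_vis = r_vis,
                 depth_threshold = depth_threshold, n_bvc = as.integer(n_bvc),
                 bvc_range = bvc_range, t_max = t_max, v_eps = v_eps,
                 noise_sigma = noise_sigma, dt = dt,
                 capture_radius = capture_radius),
            class = "control_params")
}

#' Compose a velocity vector from speed and heading
#'
#' @param s Scalar speed, m/s (>= 0).
#' @param theta Heading in radians.
#' @return Length-2 velocity `(s cos theta, s sin theta)`.
#' @export
compose_velocity <- function(s, theta) {
  stopifnot(s >= 0)
  c(s * cos(theta), s * sin(theta))
}

#' Egocentric visual scene
#'
#' Per-bin boundary distances within the BVC range, relative to the current
#' heading (bin 1 is straight ahead, successive bins rotate
#' counter-clockwise in steps of `2 pi / n_bvc`), plus target visibility.
#'
#' @param env An `environment2d`.
#' @param state Agent state list with `p` (position) and `theta` (heading).
#' @param params A [control_params()].
#' @return A list of class `visual_scene` with `d` (per-bin distances, `Inf`
#'   = clear), `d0` (straight-ahead distance), `bin_angles` (world angles),
#'   `target_visible`, `target_vector`.
#' @export
visual_scene <- function(env, state, params = control_params()) {
  offsets <- (seq_len(params$n_bvc) - 1) * 2 * pi / params$n_bvc
  angles <- state$theta + offsets
  d <- ray_distances(env, state$p, angles, params$bvc_range)
  gv <- env$target - state$p
  structure(list(d = d, d0 = d[1], bin_angles = angles,
                 bin_offsets = wrap_angle(offsets),
                 target_visible = norm2(gv) < params$r_vis,
                 target_vector = gv),
            class = "visual_scene")
}

#' BVC input drive from a visual scene
#'
#' Applies the per-channel distance tuning curve to the scene's per-bin
#' distances: `BVC_i = f(d_i)`, zero for clear bins.
#'
#' @param scene A [visual_scene()].
#' @param tuning Either a single tuning function `f(d)` (see
#'   [bvc_tuning_curve()]) or a list of one function per bin.
#' @return Numeric drive vector, one value per bin.
#' @export
bvc_drive <- function(scene, tuning) {
  if (is.function(tuning)) {
    tuning(scene$d)
  } else {
    stopifnot(length(tuning) == length(scene$d))
    vapply(seq_along(tuning), function(i) tuning[[i]](scene$d[i]),
           numeric(1))
  }
}

#' Goal attractor term
#'
#' Additional velocity component `g - p`, active only while the target is
#' inside the visibility radius.
#'
#' @param p Agent position (length 2).
#' @param g Target position (length 2).
#' @param r_vis Visibility radius, metres.
#' @return Length-2 vector.
#' @export
attractor_term <- function(p, g, r_vis = 0.3) {
  gv <- g - p
  if (norm2(gv) < r_vis) gv else c(0, 0)
}

#' Relative distance for speed control
#'
#' `(d - eps) / (D - eps)` clipped to \[0, 1\]: 0 at the minimum safety
#' distance, 1 at the critical slow-down distance.
#'
#' @param d Distance ahead, metres (`Inf` allowed).
#' @param eps Minimum safety distance.
#' @param D Critical slow-down distance.
#' @return Dimensionless value in \[0, 1\].
#' @export
relative_distance <- function(d, eps = 0.03, D = 0.4) {
  stopifnot(eps < D)
  pmin(pmax((d - eps) / (D - eps), 0), 1)
}

#' Axis speed update
#'
#' The potential speed along one axis: when an obstacle is within the
#' critical distance, speed is scaled down by the relative distance
#' (`min((|v| + v_eps) * d_hat, |v|)`, sign preserved); otherwise the agent
#' accelerates by `d_c * tau2` up to `v_max`.
#'
#' @param v_a Current axis speed, m/s.
#' @param d Distance to the obstacle ahead, metres (`Inf` = clear).
#' @param params A [control_params()].
#' @return Updated potential axis speed.
#' @export
axis_speed_update <- function(v_a, d, params = control_params()) {
  if (is.finite(d) && d < params$D) {
    dhat <- relative_distance(d, params$eps, params$D)
    sign(v_a) * min((abs(v_a) + params$v_eps) * dhat, abs(v_a))
  } else {
    min(v_a + params$d_c * params$tau2, params$v_max)
  }
}

#' Fold a potential axis speed into range
#'
#' `sign(v) * min(max(|v|, 0), v_max)`.
#'
#' @param v_a_new Axis speed, m/s.
#' @param v_max Maximal speed.
#' @return Folded speed in \[-v_max, v_max\].
#' @export
fold_potential <- function(v_a_new, v_max = 0.5) {
  sign(v_a_new) * pmin(pmax(abs(v_a_new), 0), v_max)
}

#' Steering smoothing
#'
#' Blends the newly selected steering angle with the previous one:
#' `alpha * theta_new + (1 - alpha) * theta_old`. Applied only while the
#' path ahead is blocked (`d0 < D`).
#'
#' @param theta_new Newly selected steering angle, radians, in
#'   \[-pi/2, pi/2\].
#' @param theta_old Previous steering angle.
#' @param alpha Smoothing weight of the new angle (default 0.9).
#' @return Smoothed steering angle.
#' @export
steer <- function(theta_new, theta_old, alpha = 0.9) {
  alpha * theta_new + (1 - alpha) * theta_old
}

#' 2-D rotation
#'
#' @param v Length-2 vector.
#' @param theta Rotation angle, radians (counter-clockwise).
#' @return Rotated vector `R(theta) v`.
#' @export
rotate <- function(v, theta) {
  c(cos(theta) * v[1] - sin(theta) * v[2],
    sin(theta) * v[1] + cos(theta) * v[2])
}

#' Hydrostatic-pressure heading bias
#'
#' Depth-based control: while the agent's depth differs from the target
#' depth by at least `threshold`, the commanded heading points vertically
#' toward the target depth (`+pi/2` to ascend, `-pi/2` to descend); once
#' within the band, the heading switches to the horizontal angular prior
#' `theta_hp` (0 = rightward, `pi` = leftward), which is fixed at trial
#' start and never updated.
#'
#' @param p_z Agent depth (z), metres.
#' @param g_z Target depth, metres.
#' @param theta_hp Horizontal prior, 0 or `pi`.
#' @param threshold Depth band, metres (default 0.2).
#' @return A list with `regime` (`"vertical"` or `"horizontal"`) and
#'   `heading` (the commanded heading in radians).
#' @export
hp_bias <- function(p_z, g_z, theta_hp, threshold = 0.2) {
  if (abs(p_z - g_z) < threshold) {
    list(regime = "horizontal", heading = theta_hp)
  } else {
    list(regime = "vertical",
         heading = if (g_z > p_z) pi / 2 else -pi / 2)
  }
}

#' Error-based first-order tracking update
#'
#' Smooth trajectory update: the actual value relaxes toward the potential
#' value with time constant `tau2`
#' (`d(actual)/dt = (potential - actual) / tau2`). With `wrap = TRUE`
#' the error is wrapped to the shortest arc, for heading signals.
#'
#' @param actual Current value (scalar or vector).
#' @param potential Target value.
#' @param tau2 Time constant, seconds.
#' @param dt Step, seconds.
#' @param wrap Wrap the error to (-pi, pi\] (default `FALSE`).
#' @return Updated actual value.
#' @export
error_update <- function(actual, potential, tau2 = 0.1, dt = 0.001,
                         wrap = FALSE) {
  err <- potential - actual
  if (wrap) err <- wrap_angle(err)
  actual + (1 - exp(-dt / tau2)) * err
}
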