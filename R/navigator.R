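#' Run one navigation trial
#'
#' Simulates the agent from the environment's start position until it
#' captures the target or `t_max` elapses. The control loop follows the
#' fish-inspired architecture: per-bin boundary distances feed the BVC
#' channels, a winner-take-all selection over the frontal channels picks
#' the clearest steering direction whenever the path ahead is blocked
#' (`d0 < D`), scalar speed follows the slow-down/acceleration law, heading
#' and speed relax toward their commanded values with time constant `tau2`,
#' the speed/heading conjunction is filtered with `tau1`, and position
#' integrates the (synaptically filtered) velocity plus the goal attractor.
#' In `"spiking"` mode the velocity signal is carried by a spiking LIF
#' ensemble and decoded from its filtered spike train; `"rate"` mode is the
#' deterministic limit.
#'
#' @param env An `environment2d`.
#' @param strategy A strategy from [make_strategy()].
#' @param params A [control_params()].
#' @param mode `"rate"` (deterministic) or `"spiking"`.
#' @param seed Integer seed (initial-heading draw, positional noise,
#'   ensemble construction in spiking mode).
#' @param log Record the full trajectory (default `TRUE`).
#' @return A list with `trajectory` (matrix: t, x, z, vx, vz, heading,
#'   collision) and `result` (list: reached, t_reach, time_norm, dist_norm,
#'   collision_rate, total_score, straight_dist, path_length).
#' @export
run_trial <- function(env, strategy, params = control_params(),
                      mode = c("rate", "spiking"), seed = 1L, log = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(env, "environment2d"))
  p <- env$start
  g <- env$target
  dt <- params$dt
  n_steps <- ceiling(params$t_max / dt)
  kind <- strategy$kind
  hp_like <- kind %in% c("hp", "hp_max", "hp_default")

  # unpack hot-loop constants
  v_max <- params$v_max; eps <- params$eps; D <- params$D
  d_c <- params$d_c; alpha <- params$alpha; r_vis <- params$r_vis
  depth_thr <- params$depth_threshold; v_eps <- params$v_eps
  tau1 <- params$tau1; tau2 <- params$tau2
  bvc_range <- params$bvc_range
  cap_r <- params$capture_radius
  a1 <- 1 - exp(-dt / tau1)
  a2 <- 1 - exp(-dt / tau2)
  cx <- env$coral_centers[, 1]; cz <- env$coral_centers[, 2]
  r_coral <- env$coral_radius
  r2 <- r_coral * r_coral
  b <- env$bounds
  bxmin <- b[[1]]; bxmax <- b[[2]]; bzmin <- b[[3]]; bzmax <- b[[4]]
  walls <- isTRUE(env$config$walls_are_boundaries)

  # directional bins: offsets relative to the heading, bin 1 straight ahead.
  # Only the frontal half-plane feeds the controller (d0 and the steering
  # winner-take-all), so rays are cast for those bins, ordered by |offset|
  # (counter-clockwise first) so ties prefer the least deviation.
  offs <- wrap_angle((seq_len(params$n_bvc) - 1) * 2 * pi / params$n_bvc)
  front <- which(abs(offs) <= pi / 2 + 1e-9)
  front <- front[order(abs(offs[front]), -sign(offs[front]))]
  front_offs <- offs[front]
  cos_off <- cos(front_offs); sin_off <- sin(front_offs)

  with_seed(seed, {
    bearing <- atan2(g[2] - p[2], g[1] - p[1])
    theta_hp <- if (g[1] > p[1]) 0 else pi
    base_heading <- switch(kind,
      null = bearing + stats::runif(1, -pi / 4, pi / 4),
      azimuth = bearing,
      # hp variants start in the depth-seeking or horizontal regime
      hp_bias(p[2], g[2], theta_hp, depth_thr)$heading)

    # per-bin BVC channel tuning (mean peak rate / receptive field of the
    # neurons allocated to each directional channel)
    ch <- bvc_channels(strategy, params, seed = child_seed(seed, 11L))
    rf_front <- ch$rfs[seq_along(front)]

    # spiking velocity pathway
    spiking <- mode == "spiking"
    if (spiking) {
      vel_ens <- velocity_ensemble(strategy, params,
                                   seed = child_seed(seed, 23L))
      vel_dec <- compute_decoders(vel_ens, identity,
                                  seed = child_seed(seed, 29L))
      vel_state <- ens_spike_state(
        vel_ens, c(v_max * cos(base_heading), v_max * sin(base_heading)))
    }

    theta <- base_heading    # actual heading state
    s <- v_max               # actual speed state (starts at full speed)
    v1 <- c(s * cos(theta), s * sin(theta))  # tau1-filtered velocity
    v2 <- v1                                 # tau2 (integrator synapse)
    steer_prev <- 0
    sigma <- params$noise_sigma
    if (!is.null(strategy$noise_sigma) && strategy$noise_sigma > 0)
      sigma <- strategy$noise_sigma   # strategy-level noise overrides
    noise_sd <- sigma * sqrt(dt)
    noisy <- noise_sd > 0

    traj <- if (log) matrix(NA_real_, n_steps + 1L, 7L) else NULL
    collide_n <- 0L
    total_n <- 1L
    path_len <- 0
    reached <- FALSE
    t_reach <- NA_real_

    coll <- length(cx) > 0 && any((cx - p[1])^2 + (cz - p[2])^2 < r2)
    collide_n <- collide_n + coll
    if (log) traj[1L, ] <- c(0, p[1], p[2], v2[1], v2[2], theta, coll)

    for (k in seq_len(n_steps)) {
      cth <- cos(theta); sth <- sin(theta)
      cs <- cth * cos_off - sth * sin_off
      sn <- sth * cos_off + cth * sin_off
      d <- ray_cast_core(p[1], p[2], cs, sn, cx, cz, r_coral,
                         bxmin, bxmax, bzmin, bzmax, walls, bvc_range)
      d0 <- d[1L]   # front order puts the straight-ahead bin first
      # The slow-down reflex applies to boundaries approached from outside.
      # If the agent has interpenetrated a coral (collisions are counted,
      # not hard-stopped), the ray cast sees the exit surface ahead and the
      # brake would park it just inside forever; instead it accelerates out.
      blocked <- d0 < D && !coll   # d0 is Inf when clear
      gvx <- g[1] - p[1]; gvz <- g[2] - p[2]
      visible <- (gvx * gvx + gvz * gvz) < r_vis * r_vis

      # commanded heading
      if (visible) {
        theta_cmd <- atan2(gvz, gvx)
        steer_prev <- 0
      } else if (blocked) {
        act <- pmax(1 - d / rf_front, 0)   # BVC channel activity
        act[!is.finite(d)] <- 0
        idx <- which.max(1 - act)                 # deterministic tie-break
        theta_new <- front_offs[idx]
        steer_prev <- alpha * theta_new + (1 - alpha) * steer_prev
        theta_cmd <- theta + steer_prev
      } else {
        steer_prev <- 0
        theta_cmd <- if (hp_like) {
          if (abs(p[2] - g[2]) < depth_thr) theta_hp
          else if (g[2] > p[2]) pi / 2 else -pi / 2
        } else base_heading
      }

      # potential scalar speed along the heading (axis law on the speed);
      # the v_eps boost lets a stopped agent recover while still blocked
      s_pot <- if (blocked) {
        dhat <- (d0 - eps) / (D - eps)
        if (dhat < 0) dhat <- 0
        (s + v_eps) * dhat
      } else {
        s + d_c * tau2
      }
      if (s_pot > v_max) s_pot <- v_max   # speed folding to [0, v_max]

      # error-based first-order tracking of speed and heading
      s <- s + a2 * (s_pot - s)
      derr <- (theta_cmd - theta + pi) %% (2 * pi) - pi
      theta <- theta + a2 * derr

      # speed/heading conjunction from the tracked states (the commanded
      # heading can jump with the winner-take-all; the tracked heading is
      # what the motor population carries), then the tau1 synapse
      v_cmd <- c(s * cos(theta), s * sin(theta))
      if (spiking) {
        st <- ens_spike_step(vel_ens, v_cmd, vel_state, dt)
        vel_state <- st$state
        v_dec <- drop(matrix(st$spikes, 1) %*% vel_dec)
        v1 <- v1 + a1 * (v_dec - v1)
      } else {
        v1 <- v1 + a1 * (v_cmd - v1)
      }
      # integrator synapse (tau2), then position update with attractor
      v2 <- v2 + a2 * (v1 - v2)
      px <- p[1] + v2[1] * dt
      pz <- p[2] + v2[2] * dt
      if (visible) {           # goal attractor g - p
        px <- px + gvx * dt
        pz <- pz + gvz * dt
      }
      if (noisy) {
        nn <- stats::rnorm(2, 0, noise_sd)
        px <- px + nn[1]; pz <- pz + nn[2]
      }
      # arena walls are physical: clamp inside bounds
      if (px < bxmin) px <- bxmin else if (px > bxmax) px <- bxmax
      if (pz < bzmin) pz <- bzmin else if (pz > bzmax) pz <- bzmax
      path_len <- path_len + sqrt((px - p[1])^2 + (pz - p[2])^2)
      p[1] <- px; p[2] <- pz

      if (is.na(px) || is.na(pz))
        stop("simulation diverged at t = ", k * dt)

      coll <- length(cx) > 0 && any((cx - px)^2 + (cz - pz)^2 < r2)
      collide_n <- collide_n + coll
      total_n <- total_n + 1L
      if (log) traj[total_n, ] <- c(k * dt, px, pz, v2[1], v2[2], theta,
                                    coll)

      if ((g[1] - px)^2 + (g[2] - pz)^2 < cap_r * cap_r) {
        reached <- TRUE
        t_reach <- k * dt
        break
      }
    }

    if (log) {
      traj <- traj[seq_len(total_n), , drop = FALSE]
      colnames(traj) <- c("t", "x", "z", "vx", "vz", "heading", "collision")
    }
    straight <- norm2(g - env$start)
    res <- list(
      reached = reached, t_reach = t_reach,
      time_norm = if (reached)
        time_to_target_norm(t_reach, straight, v_max, params$t_max)
        else NA_real_,
      dist_norm = if (reached)
        distance_norm(path_len, straight, v_max, params$t_max)
        else NA_real_,
      collision_rate = collide_n / total_n,
      straight_dist = straight, path_length = path_len
    )
    res$total_score <- total_score(res)
    list(trajectory = traj, result = res)
  })
}

# Channel BVC tuning: the BVC array is an array of *identical* ensembles,
# one per direction, so every channel responds with the same population
# tuning curve -- here its mean peak rate and mean receptive field over the
# sampled neurons.
bvc_channels <- function(strategy, params, seed = 1L) {
  n_bvc <- max(strategy$counts[["bvc"]], params$n_bvc)
  tun <- sample_bvc_tuning(n_bvc, strategy$spec, seed = seed)
  mr <- mean(tun$max_rates) * strategy$rate_scale
  rf <- mean(tun$receptive_fields)
  list(max_rates = rep(mr, params$n_bvc), rfs = rep(rf, params$n_bvc),
       n_bins = params$n_bvc)
}

# Clearness utilities over the frontal channels (offsets within [-pi/2,
# pi/2]), ordered by |offset| so the winner-take-all tie-break prefers the
# least deviation from the current heading.
channel_clearness <- function(scene, ch) {
  off <- scene$bin_offsets
  front <- which(abs(off) <= pi / 2 + 1e-9)
  ord <- front[order(abs(off[front]), -sign(off[front]))]
  d <- scene$d[ord]
  act <- pmax(1 - d / ch$rfs[ord], 0)   # normalized BVC channel activity
  act[!is.finite(d)] <- 0
  list(utilities = 1 - act, offsets = off[ord])
}

# Spiking ensemble carrying the 2-D velocity signal.
velocity_ensemble <- function(strategy, params, seed = 1L) {
  n <- max(10L, as.integer(strategy$counts[["velocity"]]))
  rates <- with_seed(seed, sample_rates(n, strategy$spec$max_rate_dist))
  rates <- pmax(rates * strategy$rate_scale, 0.1)
  nef_ensemble(n, dim = 2, max_rates = rates,
               # the folding law bounds |v_cmd| by v_max and the synaptic
               # low-passes are convex, so v_max covers the whole signal range
               neuron_kind = "lif", radius = params$v_max,
               tau_rc = strategy$spec$tau_rc,
               tau_ref = strategy$spec$tau_ref, seed = seed)
}
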