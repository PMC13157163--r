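#' Arena configuration
#'
#' Describes a square virtual arena: a vertical slice of the water column,
#' `width` metres of horizontal extent (x) by `height` metres of depth (z),
#' centred on the origin, populated with circular coral obstacles.
#'
#' @param width Horizontal extent in metres (default 4, i.e. x in
#'   \[-2, 2\]).
#' @param height Vertical extent (depth) in metres (default 4, z in
#'   \[-2, 2\]).
#' @param n_corals Number of circular obstacles (default 25, the midpoint of
#'   the usual 20--30 range).
#' @param coral_radius Obstacle radius in metres (default 0.15).
#' @param v_max Maximal swimming speed in m/s (default 0.5).
#' @param t_max Maximal simulation time in seconds (default 45).
#' @param walls_are_boundaries Should the arena walls be visible to the
#'   boundary ray-cast (default `TRUE`)? BVCs respond to any boundary, and
#'   with this on the agent treats walls like coral surfaces.
#'
#' @return An object of class `arena_config`.
#' @export
arena_config <- function(width = 4, height = 4, n_corals = 25,
                         coral_radius = 0.15, v_max = 0.5, t_max = 45,
                         walls_are_boundaries = TRUE) {
  stopifnot(width > 0, height > 0, n_corals >= 0, coral_radius > 0,
            v_max > 0, t_max > 0)
  structure(
    list(width = width, height = height, n_corals = as.integer(n_corals),
         coral_radius = coral_radius, v_max = v_max, t_max = t_max,
         walls_are_boundaries = isTRUE(walls_are_boundaries)),
    class = "arena_config"
  )
}

#' Generate a seeded virtual arena
#'
#' Places `n_corals` coral disks uniformly inside the arena and samples a
#' start and a target position in opposite quadrants (rejection-sampled so
#' that neither lies inside or within a small clearance of a coral).
#' Optionally the start/target can be pinned (as in the A* comparison,
#' which uses (-1.8, -1.8) and (1.8, 1.8)); pinned positions are protected
#' by the same clearance during coral placement.
#'
#' @param config An [arena_config()].
#' @param seed Integer seed; the same `(config, seed)` pair always yields an
#'   identical environment.
#' @param start,target Optional fixed 2-column positions; when `NULL`
#'   (default) they are sampled in randomly chosen opposite quadrants.
#' @param clearance Minimum distance between a coral *surface* and the
#'   start/target points (default 0.05 m), so that endpoints never begin in
#'   contact with an obstacle.
#'
#' @return An object of class `environment2d` with fields `coral_centers`
#'   (n x 2 matrix), `start`, `target` (length-2 vectors), `bounds`
#'   (xmin, xmax, zmin, zmax), `coral_radius`, `config`, `seed`.
#' @export
generate_environment <- function(config = arena_config(), seed = 1L,
                                 start = NULL, target = NULL,
                                 clearance = 0.05) {
  stopifnot(inherits(config, "arena_config"))
  hw <- config$width / 2
  hh <- config$height / 2
  bounds <- c(xmin = -hw, xmax = hw, zmin = -hh, zmax = hh)
  r <- config$coral_radius

  with_seed(seed, {
    if (is.null(start) || is.null(target)) {
      # opposite quadrants: pick one of the 4 quadrants for the start, the
      # diagonally opposite one for the target
      qs <- sample.int(4L, 1L)       # 1: (+,+), 2: (-,+), 3: (-,-), 4: (+,-)
      qt <- ((qs + 1L) %% 4L) + 1L   # diagonal opposite
      sq <- quadrant_sign(qs)
      tq <- quadrant_sign(qt)
      if (is.null(start))
        start <- c(stats::runif(1, 0.1 * hw, 0.95 * hw) * sq[1],
                   stats::runif(1, 0.1 * hh, 0.95 * hh) * sq[2])
      if (is.null(target))
        target <- c(stats::runif(1, 0.1 * hw, 0.95 * hw) * tq[1],
                    stats::runif(1, 0.1 * hh, 0.95 * hh) * tq[2])
    }
    start <- as.numeric(start); target <- as.numeric(target)
    keep_out <- r + clearance
    centers <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(centers) < config$n_corals) {
      tries <- tries + 1L
      if (tries > 1000L * max(1L, config$n_corals))
        stop("arena too small: could not place ", config$n_corals,
             " corals without covering start/target")
      cand <- c(stats::runif(1, -hw + r, hw - r),
                stats::runif(1, -hh + r, hh - r))
      if (sqrt(sum((cand - start)^2))  < keep_out) next
      if (sqrt(sum((cand - target)^2)) < keep_out) next
      centers <- rbind(centers, cand)
    }
    dimnames(centers) <- NULL
    structure(
      list(coral_centers = centers, start = start, target = target,
           bounds = bounds, coral_radius = r, config = config,
           seed = as.integer(seed)),
      class = "environment2d"
    )
  })
}

quadrant_sign <- function(q) {
  switch(q, c(1, 1), c(-1, 1), c(-1, -1), c(1, -1))
}

#' @export
print.environment2d <- function(x, ...) {
  cat(sprintf("<environment2d> %g x %g m, %d corals (r = %g m), seed %d\n",
              x$config$width, x$config$height, nrow(x$coral_centers),
              x$coral_radius, x$seed))
  cat(sprintf("  start  (%.3f, %.3f)\n  target (%.3f, %.3f)\n",
              x$start[1], x$start[2], x$target[1], x$target[2]))
  invisible(x)
}

#' Angular aperture of a coral
#'
#' The angular extent that a circular obstacle of radius `r` at distance `d`
#' (to its centre) subtends in the agent's visual field: `2 * atan(r / d)`.
#'
#' @param d Distance from the agent to the coral centre, metres (> 0).
#' @param r Coral radius in metres (> 0).
#' @return Aperture in radians.
#' @export
coral_aperture <- function(d, r) {
  if (any(d <= 0)) stop("coral_aperture: distance d must be > 0")
  if (any(r <= 0)) stop("coral_aperture: radius r must be > 0")
  2 * atan(r / d)
}

#' Distance to the nearest boundary along a ray
#'
#' Casts a ray from `pos` at world angle `angle` (counter-clockwise from +x)
#' and returns the distance to the nearest boundary surface -- a coral
#' perimeter or, when `walls_are_boundaries` is set in the config, an arena
#' wall -- or `Inf` ("clear") if none lies within `max_range`.
#'
#' @param env An `environment2d`.
#' @param pos Length-2 position inside the bounds.
#' @param angle Ray direction in radians.
#' @param max_range Sensing range in metres (default 1.4).
#' @return Distance in metres, or `Inf` when clear.
#' @export
distance_along_direction <- function(env, pos, angle, max_range = 1.4) {
  stopifnot(max_range > 0)
  d <- ray_distances(env, pos, angle, max_range)
  d[1]
}

# Vectorized ray cast: distances from pos along each angle to the nearest
# coral surface or wall, Inf where nothing lies within max_range.
ray_distances <- function(env, pos, angles, max_range = 1.4) {
  centers <- env$coral_centers
  b <- env$bounds
  ray_cast_core(pos[1], pos[2], cos(angles), sin(angles),
                centers[, 1], centers[, 2], env$coral_radius,
                b[[1]], b[[2]], b[[3]], b[[4]],
                isTRUE(env$config$walls_are_boundaries), max_range)
}

# Hot-path core: all arguments unpacked scalars/vectors.
ray_cast_core <- function(px, pz, cs, sn, cx, cz, r,
                          bxmin, bxmax, bzmin, bzmax, walls, max_range) {
  n <- length(cs)
  d <- rep(Inf, n)
  if (length(cx) > 0) {
    wx <- cx - px
    wz <- cz - pz
    dc2 <- wx * wx + wz * wz
    near <- which(dc2 <= (max_range + r)^2)
    if (length(near) > 0) {
      for (i in near) {
        # ray-circle: t^2 - 2 (w.u) t + (|w|^2 - r^2) = 0
        wu <- cs * wx[i] + sn * wz[i]
        c0 <- dc2[i] - r * r
        disc <- wu * wu - c0
        sq <- sqrt(pmax(disc, 0))
        # strictly inside the disk (c0 < 0): the boundary surface along
        # the ray is the exit point, i.e. the far intersection
        tt <- if (c0 < 0) wu + sq else wu - sq
        tt[disc < 0 | tt < 0] <- Inf
        d <- pmin(d, tt)
      }
    }
  }
  if (walls) {
    tx <- ((cs > 0) * (bxmax - px) + (cs < 0) * (bxmin - px)) / cs
    tz <- ((sn > 0) * (bzmax - pz) + (sn < 0) * (bzmin - pz)) / sn
    tx[is.nan(tx)] <- Inf
    tz[is.nan(tz)] <- Inf
    tw <- pmin(tx, tz)
    tw[tw < 0] <- 0   # already on/over a wall
    d <- pmin(d, tw)
  }
  d[d > max_range] <- Inf
  d
}

#' Angular bins affected by a single coral
#'
#' Determines which of `n_bins` uniformly spaced directional bins fall
#' within the coral's aperture around its bearing, and the per-direction
#' boundary distance for each affected bin. Bin `i` (1-based) has centre
#' direction `heading + (i - 1) * 2 * pi / n_bins`.
#'
#' @param env An `environment2d`.
#' @param pos Agent position (length 2).
#' @param coral Coral centre (length 2).
#' @param n_bins Number of angular bins (default 24).
#' @param max_range Sensing range in metres (default 1.4).
#' @param heading Reference direction of bin 1 in radians (default 0).
#' @return A data frame with columns `bin` and `distance`; zero rows when
#'   the coral is out of range.
#' @export
affected_bins <- function(env, pos, coral, n_bins = 24, max_range = 1.4,
                          heading = 0) {
  stopifnot(n_bins >= 1)
  w <- coral - pos
  dc <- sqrt(sum(w^2))
  r <- env$coral_radius
  if (dc - r > max_range || dc == 0)
    return(data.frame(bin = integer(0), distance = numeric(0)))
  bearing <- atan2(w[2], w[1])
  half_ap <- atan(r / dc)  # half aperture (dc > r assumed for aperture calc)
  if (dc <= r) half_ap <- pi  # agent inside the disk: all bins affected
  bin_angles <- heading + (seq_len(n_bins) - 1) * 2 * pi / n_bins
  delta <- abs(wrap_angle(bin_angles - bearing))
  hit <- which(delta <= half_ap)
  if (length(hit) == 0)
    return(data.frame(bin = integer(0), distance = numeric(0)))
  # per-direction distance restricted to this one coral
  env1 <- env
  env1$coral_centers <- matrix(coral, 1, 2)
  env1$config$walls_are_boundaries <- FALSE
  dd <- ray_distances(env1, pos, bin_angles[hit], max_range)
  keep <- is.finite(dd)
  data.frame(bin = hit[keep], distance = dd[keep])
}

#' Collision test
#'
#' A position collides when its distance to any coral *centre* is strictly
#' smaller than the coral radius (the same criterion used by the collision
#' rate metric).
#'
#' @param env An `environment2d`.
#' @param pos Length-2 position.
#' @return `TRUE`/`FALSE`.
#' @export
check_collision <- function(env, pos) {
  centers <- env$coral_centers
  if (nrow(centers) == 0) return(FALSE)
  dx <- centers[, 1] - pos[1]
  dz <- centers[, 2] - pos[2]
  any(dx * dx + dz * dz < env$coral_radius^2)
}

#' Serialize / deserialize an environment to JSON
#'
#' @param env An `environment2d`.
#' @param path File path.
#' @return `write_environment` returns `path` invisibly; `read_environment`
#'   returns the `environment2d`.
#' @export
write_environment <- function(env, path) {
  obj <- list(
    width = env$config$width, height = env$config$height,
    coral_radius = env$coral_radius, v_max = env$config$v_max,
    t_max = env$config$t_max,
    walls_are_boundaries = env$config$walls_are_boundaries,
    coral_centers = env$coral_centers, start = env$start,
    target = env$target, seed = env$seed
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_environment
#' @export
read_environment <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- arena_config(width = obj$width, height = obj$height,
                      n_corals = nrow_or0(obj$coral_centers),
                      coral_radius = obj$coral_radius, v_max = obj$v_max,
                      t_max = obj$t_max,
                      walls_are_boundaries = obj$walls_are_boundaries)
  centers <- obj$coral_centers
  if (is.null(centers) || length(centers) == 0) {
    centers <- matrix(numeric(0), 0, 2)
  } else {
    centers <- matrix(as.numeric(centers), ncol = 2)
  }
  structure(
    list(coral_centers = centers, start = as.numeric(obj$start),
         target = as.numeric(obj$target),
         bounds = c(xmin = -obj$width / 2, xmax = obj$width / 2,
                    zmin = -obj$height / 2, zmax = obj$height / 2),
         coral_radius = obj$coral_radius, config = cfg,
         seed = as.integer(obj$seed)),
    class = "environment2d"
  )
}

nrow_or0 <- function(x) if (is.null(x) || length(x) == 0) 0L else nrow(matrix(as.numeric(x), ncol = 2))
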