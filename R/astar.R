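#' Occupancy grid map of an environment
#'
#' Rasterizes the arena onto a square lattice: cell (1, 1) sits at the
#' lower-left corner, cell centres at `(xmin + (i - 0.5) * res,
#' zmin + (j - 0.5) * res)`, and a cell is occupied iff its centre lies
#' within any of the *known* coral disks.
#'
#' @param env An `environment2d`.
#' @param resolution Cell size in metres (default 0.05).
#' @param known_corals Row indices of `env$coral_centers` to rasterize
#'   (default all); the local-sensing agent passes only the corals it has
#'   seen.
#' @return An object of class `grid_map` with `occupancy` (logical vector,
#'   column-major by z-row), `nx`, `nz`, `resolution`, `origin`.
#' @export
grid_map <- function(env, resolution = 0.05, known_corals = NULL) {
  b <- env$bounds
  nx <- round((b[["xmax"]] - b[["xmin"]]) / resolution)
  nz <- round((b[["zmax"]] - b[["zmin"]]) / resolution)
  origin <- c(b[["xmin"]], b[["zmin"]])
  centers <- env$coral_centers
  if (!is.null(known_corals)) centers <- centers[known_corals, , drop = FALSE]
  occ <- rep(FALSE, nx * nz)
  if (nrow(centers) > 0) {
    cx <- origin[1] + (seq_len(nx) - 0.5) * resolution
    cz <- origin[2] + (seq_len(nz) - 0.5) * resolution
    r2 <- env$coral_radius^2
    for (i in seq_len(nrow(centers))) {
      ix <- which(abs(cx - centers[i, 1]) <= env$coral_radius)
      iz <- which(abs(cz - centers[i, 2]) <= env$coral_radius)
      if (length(ix) == 0 || length(iz) == 0) next
      dd <- outer((cx[ix] - centers[i, 1])^2, (cz[iz] - centers[i, 2])^2, "+")
      hit <- which(dd < r2, arr.ind = TRUE)
      if (nrow(hit) > 0)
        occ[(iz[hit[, 2]] - 1L) * nx + ix[hit[, 1]]] <- TRUE
    }
  }
  structure(list(occupancy = occ, nx = as.integer(nx), nz = as.integer(nz),
                 resolution = resolution, origin = origin),
            class = "grid_map")
}

#' @rdname grid_map
#' @param pos Length-2 position in metres.
#' @return `grid_cell_of` returns the linear cell index of a position;
#'   `cell_center` its metric centre coordinates.
#' @export
grid_cell_of <- function(grid, pos) {
  ix <- pmin(pmax(floor((pos[1] - grid$origin[1]) / grid$resolution) + 1L,
                  1L), grid$nx)
  iz <- pmin(pmax(floor((pos[2] - grid$origin[2]) / grid$resolution) + 1L,
                  1L), grid$nz)
  as.integer((iz - 1L) * grid$nx + ix)
}

#' @rdname grid_map
#' @param grid A `grid_map`.
#' @param idx Linear cell index.
#' @export
cell_center <- function(grid, idx) {
  ix <- ((idx - 1L) %% grid$nx) + 1L
  iz <- ((idx - 1L) %/% grid$nx) + 1L
  cbind(grid$origin[1] + (ix - 0.5) * grid$resolution,
        grid$origin[2] + (iz - 0.5) * grid$resolution)
}

#' A* grid planner
#'
#' Optimal 8-connected path under octile edge costs (`res` straight,
#' `res * sqrt(2)` diagonal) with the admissible Euclidean heuristic.
#' Tie-breaking is deterministic: lower f, then lower heuristic, then lower
#' cell index.
#'
#' @param grid A [grid_map()].
#' @param start,goal Linear cell indices (or length-2 metre positions).
#' @return A list with `found`, `path` (linear indices, empty when
#'   `start == goal`), `coords` (metre waypoints), `cost` (metres; `Inf` on
#'   failure).
#' @export
astar_plan <- function(grid, start, goal) {
  if (length(start) == 2) start <- grid_cell_of(grid, start)
  if (length(goal) == 2) goal <- grid_cell_of(grid, goal)
  if (grid$occupancy[start]) stop("astar_plan: start cell occupied")
  if (grid$occupancy[goal]) stop("astar_plan: goal cell occupied")
  if (start == goal)
    return(list(found = TRUE, path = integer(0),
                coords = matrix(numeric(0), 0, 2), cost = 0))

  nx <- grid$nx; nz <- grid$nz; res <- grid$resolution
  nv <- nx * nz
  gx <- ((goal - 1L) %% nx) + 1L
  gz <- ((goal - 1L) %/% nx) + 1L
  h_of <- function(idx) {
    ix <- ((idx - 1L) %% nx) + 1L
    iz <- ((idx - 1L) %/% nx) + 1L
    res * sqrt((ix - gx)^2 + (iz - gz)^2)
  }
  dxs <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  dzs <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  step_cost <- res * ifelse(dxs != 0 & dzs != 0, sqrt(2), 1)

  gsc <- rep(Inf, nv)
  fkey <- rep(Inf, nv)   # f with deterministic tie-break perturbation
  came <- integer(nv)
  closed <- rep(FALSE, nv)
  gsc[start] <- 0
  fkey[start] <- h_of(start) * (1 + 1e-9)
  open_f <- rep(Inf, nv)
  open_f[start] <- fkey[start]

  repeat {
    cur <- which.min(open_f)
    if (!is.finite(open_f[cur]))
      return(list(found = FALSE, path = integer(0),
                  coords = matrix(numeric(0), 0, 2), cost = Inf))
    open_f[cur] <- Inf
    if (closed[cur]) next
    closed[cur] <- TRUE
    if (cur == goal) break
    cix <- ((cur - 1L) %% nx) + 1L
    ciz <- ((cur - 1L) %/% nx) + 1L
    nxs <- cix + dxs
    nzs <- ciz + dzs
    ok <- nxs >= 1L & nxs <= nx & nzs >= 1L & nzs <= nz
    nbr <- (nzs[ok] - 1L) * nx + nxs[ok]
    sc <- step_cost[ok]
    free <- !grid$occupancy[nbr] & !closed[nbr]
    nbr <- nbr[free]; sc <- sc[free]
    if (length(nbr) == 0) next
    tent <- gsc[cur] + sc
    better <- tent < gsc[nbr] - 1e-12
    if (any(better)) {
      nb <- nbr[better]
      gsc[nb] <- tent[better]
      came[nb] <- cur
      hh <- h_of(nb)
      # key orders by f, then h, then index, all strictly dominated by
      # genuine octile cost differences
      key <- (gsc[nb] + hh) + hh * 1e-7 + nb * 1e-12
      fkey[nb] <- key
      open_f[nb] <- key
    }
  }

  path <- goal
  while (path[1] != start) path <- c(came[path[1]], path)
  path <- path[-1]   # exclude the start cell
  list(found = TRUE, path = path, coords = cell_center(grid, path),
       cost = gsc[goal])
}

#' A* agent configuration
#'
#' @param mode `"global"` (full obstacle map available to the planner) or
#'   `"local"` (obstacles sensed only within `sensing_radius`, with online
#'   replanning).
#' @param sensing_radius Local sensing radius in metres (default 1.4, the
#'   same range as the BVC system).
#' @param replan_rate Sensing/replanning rate in Hz (default 20).
#' @param speed Travel speed, m/s (default 0.5).
#' @param resolution Grid resolution in metres (default 0.05).
#' @return An object of class `astar_config`.
#' @export
astar_config <- function(mode = c("global", "local"), sensing_radius = 1.4,
                         replan_rate = 20, speed = 0.5, resolution = 0.05) {
  mode <- match.arg(mode)
  structure(list(mode = mode, sensing_radius = sensing_radius,
                 replan_rate = replan_rate, speed = speed,
                 resolution = resolution),
            class = "astar_config")
}

#' Run the A* agent on an environment
#'
#' Global mode plans once on the full map and follows the path at constant
#' speed. Local mode starts with an empty obstacle map, senses coral
#' centres within the sensing radius at the replanning rate, accretes them
#' into its map, and replans whenever the map changes (a plan on an
#' unchanged map is identical, so replanning is triggered by new
#' information). The trajectory is sampled at the replanning rate and
#' scored with the same metrics as the neural agent.
#'
#' @param env An `environment2d`.
#' @param config An [astar_config()].
#' @return A list with `trajectory` (t, x, z, collision) and `result` (as
#'   in [run_trial()]).
#' @export
astar_run_agent <- function(env, config = astar_config()) {
  t_max <- env$config$t_max
  v <- config$speed
  dt <- 1 / config$replan_rate
  p <- env$start
  g <- env$target
  straight <- norm2(g - p)

  if (config$mode == "global") {
    grid <- grid_map(env, config$resolution)
    plan <- astar_plan(grid, p, g)
    if (!plan$found) {
      tr0 <- matrix(c(0, p, check_collision(env, p)), 1,
                    dimnames = list(NULL, c("t", "x", "z", "collision")))
      return(astar_result(env, tr0, FALSE, NA_real_, 0, straight))
    }
    waypoints <- rbind(plan$coords, g)
    return(follow_waypoints(env, waypoints, v, dt, t_max, straight))
  }

  # Local mode: sense at the replanning rate, accrete sensed corals into the
  # map, and replan whenever new information has arrived (a plan on an
  # unchanged map is identical, so replanning is triggered by map changes).
  # Replanning takes effect at the next cell centre the agent passes, so the
  # executed path is always a valid grid path: any grid path from start to
  # goal costs at least the globally optimal cost, which keeps the
  # local-path-length >= global-path-length optimality oracle exact.
  n_corals <- nrow(env$coral_centers)
  known <- rep(FALSE, n_corals)
  grid <- grid_map(env, config$resolution, known_corals = integer(0))
  goal_cell <- grid_cell_of(grid, g)
  n_steps <- ceiling(t_max / dt)
  traj <- matrix(NA_real_, n_steps + 1L, 4L)
  traj[1L, ] <- c(0, p, check_collision(env, p))
  waypoints <- NULL
  dirty <- TRUE      # map (or plan) is out of date
  failed <- FALSE
  reached <- FALSE
  t_reach <- NA_real_
  plen <- 0
  k_used <- 1L

  replan <- function(from) {
    start_cell <- grid_cell_of(grid, from)
    if (grid$occupancy[start_cell])
      grid$occupancy[start_cell] <<- FALSE  # the agent is here
    astar_plan(grid, start_cell, goal_cell)
  }

  for (k in seq_len(n_steps)) {
    # sense and accrete
    if (n_corals > 0) {
      dx <- env$coral_centers[, 1] - p[1]
      dz <- env$coral_centers[, 2] - p[2]
      seen <- (dx * dx + dz * dz) <= config$sensing_radius^2
      if (any(seen & !known)) {
        known <- known | seen
        grid <- grid_map(env, config$resolution,
                         known_corals = which(known))
        dirty <- TRUE
      }
    }
    if (is.null(waypoints)) {    # initial plan, from the start position
      plan <- replan(p)
      if (!plan$found) { failed <- TRUE; break }
      waypoints <- rbind(plan$coords, g)
      dirty <- FALSE
    }
    # advance one tick; a pending replan takes effect at the next waypoint
    # (cell centre) so motion stays on grid edges
    budget <- v * dt
    while (budget > 1e-12 && nrow(waypoints) > 0) {
      w <- waypoints[1, ]
      seg <- norm2(w - p)
      if (seg <= budget) {
        p <- w
        plen <- plen + seg
        budget <- budget - seg
        waypoints <- waypoints[-1, , drop = FALSE]
        if (dirty && nrow(waypoints) > 0) {
          plan <- replan(p)
          if (!plan$found) { failed <- TRUE; break }
          waypoints <- rbind(plan$coords, g)
          dirty <- FALSE
        }
      } else {
        p <- p + (w - p) * (budget / seg)
        plen <- plen + budget
        budget <- 0
      }
    }
    k_used <- k + 1L
    traj[k_used, ] <- c(k * dt, p, check_collision(env, p))
    if (failed) break
    if (nrow(waypoints) == 0) {
      reached <- TRUE
      t_reach <- k * dt
      break
    }
  }
  traj <- traj[seq_len(k_used), , drop = FALSE]
  colnames(traj) <- c("t", "x", "z", "collision")
  astar_result(env, traj, reached, t_reach, plen, straight)
}

# Move dist metres along the waypoint list; returns new position, remaining
# waypoints and distance actually travelled.
advance_along <- function(p, waypoints, dist) {
  travelled <- 0
  while (dist > 1e-12 && nrow(waypoints) > 0) {
    w <- waypoints[1, ]
    seg <- norm2(w - p)
    if (seg <= dist) {
      p <- w
      travelled <- travelled + seg
      dist <- dist - seg
      waypoints <- waypoints[-1, , drop = FALSE]
    } else {
      p <- p + (w - p) * (dist / seg)
      travelled <- travelled + dist
      dist <- 0
    }
  }
  list(pos = p, waypoints = waypoints, travelled = travelled)
}

# Global-mode kinematics: follow the fixed waypoint list at constant speed,
# sampling the trajectory at dt.
follow_waypoints <- function(env, waypoints, v, dt, t_max, straight) {
  p <- env$start
  n_steps <- ceiling(t_max / dt)
  traj <- matrix(NA_real_, n_steps + 1L, 4L)
  traj[1L, ] <- c(0, p, check_collision(env, p))
  plen <- 0
  reached <- FALSE
  t_reach <- NA_real_
  k_used <- 1L
  for (k in seq_len(n_steps)) {
    mv <- advance_along(p, waypoints, v * dt)
    plen <- plen + mv$travelled
    p <- mv$pos
    waypoints <- mv$waypoints
    k_used <- k + 1L
    traj[k_used, ] <- c(k * dt, p, check_collision(env, p))
    if (nrow(waypoints) == 0) {
      reached <- TRUE
      t_reach <- k * dt
      break
    }
  }
  traj <- traj[seq_len(k_used), , drop = FALSE]
  colnames(traj) <- c("t", "x", "z", "collision")
  astar_result(env, traj, reached, t_reach, plen, straight)
}

astar_result <- function(env, traj, reached, t_reach, plen, straight) {
  v_max <- env$config$v_max
  t_max <- env$config$t_max
  res <- list(
    reached = reached, t_reach = t_reach,
    time_norm = if (reached)
      time_to_target_norm(t_reach, straight, v_max, t_max) else NA_real_,
    dist_norm = if (reached)
      distance_norm(plen, straight, v_max, t_max) else NA_real_,
    collision_rate = mean(traj[, "collision"]),
    straight_dist = straight, path_length = plen
  )
  res$total_score <- total_score(res)
  list(trajectory = traj, result = res)
}
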