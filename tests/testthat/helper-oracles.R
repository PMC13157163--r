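# Independent oracles used across test files.

# Brute-force DTW: enumerate every monotone warping path between two short
# point sequences and return the minimal summed Euclidean cost.
dtw_bruteforce <- function(a, b) {
  na <- nrow(a)
  nb <- nrow(b)
  cost <- function(i, j) sqrt(sum((a[i, ] - b[j, ])^2))
  best <- Inf
  walk <- function(i, j, acc) {
    acc <- acc + cost(i, j)
    if (acc >= best) return(invisible())
    if (i == na && j == nb) {
      best <<- acc
      return(invisible())
    }
    if (i < na) walk(i + 1, j, acc)
    if (j < nb) walk(i, j + 1, acc)
    if (i < na && j < nb) walk(i + 1, j + 1, acc)
    invisible()
  }
  walk(1, 1, 0)
  best
}

# Dijkstra shortest-path cost on a grid_map via igraph, 8-connected with
# octile edge weights; an independent reference for the A* planner.
dijkstra_grid_cost <- function(grid, start, goal) {
  nx <- grid$nx
  nz <- grid$nz
  res <- grid$resolution
  from <- integer(0)
  to <- integer(0)
  w <- numeric(0)
  for (dz in c(0L, 1L)) {
    for (dx in if (dz == 0L) 1L else c(-1L, 0L, 1L)) {
      ix <- seq_len(nx)
      iz <- seq_len(nz)
      ix_ok <- ix[ix + dx >= 1L & ix + dx <= nx]
      iz_ok <- iz[iz + dz >= 1L & iz + dz <= nz]
      if (length(ix_ok) == 0 || length(iz_ok) == 0) next
      a <- as.vector(outer(ix_ok, (iz_ok - 1L) * nx, `+`))
      b <- as.vector(outer(ix_ok + dx, (iz_ok + dz - 1L) * nx, `+`))
      keep <- !grid$occupancy[a] & !grid$occupancy[b]
      from <- c(from, a[keep])
      to <- c(to, b[keep])
      w <- c(w, rep(res * sqrt(dx * dx + dz * dz), sum(keep)))
    }
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nx * nz - igraph::vcount(g)))
  igraph::E(g)$weight <- w
  as.numeric(igraph::distances(g, v = start, to = goal))
}

# Build a small environment and plant corals at given centers.
env_with_corals <- function(centers, width = 4, height = 4,
                            walls = TRUE, start = c(-1.8, -1.8),
                            target = c(1.8, 1.8)) {
  env <- generate_environment(
    arena_config(width = width, height = height, n_corals = 0,
                 walls_are_boundaries = walls),
    seed = 1L, start = start, target = target)
  env$coral_centers <- matrix(centers, ncol = 2, byrow = TRUE)
  env
}
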