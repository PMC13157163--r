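test_that("environment generation is seeded, bounded and quadrant-opposed", {
  cfg <- arena_config()
  e1 <- generate_environment(cfg, seed = 11L)
  e2 <- generate_environment(cfg, seed = 11L)
  expect_identical(e1, e2)

  e3 <- generate_environment(cfg, seed = 12L)
  expect_false(identical(e1$coral_centers, e3$coral_centers))

  for (s in 1:10) {
    e <- generate_environment(cfg, seed = s)
    expect_equal(nrow(e$coral_centers), 25)
    expect_true(all(abs(e$coral_centers) <= 2 - e$coral_radius + 1e-12))
    # start and target in diagonally opposite quadrants
    expect_true(all(sign(e$start) * sign(e$target) < 0))
    # endpoints keep clear of every coral surface
    dmin <- function(p) min(sqrt(rowSums(sweep(e$coral_centers, 2, p)^2)))
    expect_gte(dmin(e$start), e$coral_radius + 0.05)
    expect_gte(dmin(e$target), e$coral_radius + 0.05)
  }

  e0 <- generate_environment(arena_config(n_corals = 0), seed = 1L)
  expect_equal(nrow(e0$coral_centers), 0)

  # impossible placement errors out instead of looping forever
  expect_error(
    generate_environment(arena_config(width = 0.42, height = 0.42,
                                      n_corals = 50), seed = 1L),
    "arena too small")
})

test_that("coral aperture follows 2 atan(r/d)", {
  expect_equal(coral_aperture(0.15, 0.15), pi / 2)
  expect_equal(coral_aperture(1.4, 0.15), 0.2134713, tolerance = 1e-6)
  expect_lt(coral_aperture(1e6, 0.15), 1e-5)
  d <- seq(0.2, 1.4, by = 0.1)
  expect_true(all(diff(coral_aperture(d, 0.15)) < 0))
  expect_error(coral_aperture(0, 0.15), "must be > 0")
  expect_error(coral_aperture(1, -1), "must be > 0")
})

test_that("ray casting matches ray-circle and wall geometry", {
  env <- env_with_corals(c(1, 0), walls = FALSE, start = c(0, 0))
  # coral of radius 0.15 centered 1 m dead ahead -> surface at 0.85 m
  expect_equal(distance_along_direction(env, c(0, 0), 0), 0.85)
  # from the perimeter, into the coral -> 0
  expect_equal(distance_along_direction(env, c(0.85, 0), 0), 0)
  # pointing away -> clear
  expect_identical(distance_along_direction(env, c(0, 0), pi), Inf)
  # beyond sensing range -> clear
  expect_identical(distance_along_direction(env, c(-0.6, 0), 0), Inf)

  # walls as boundaries: 1 m from the x = 2 wall
  envw <- env_with_corals(c(1, 5), walls = TRUE, start = c(0, 0))
  envw$coral_centers <- matrix(numeric(0), 0, 2)
  expect_identical(distance_along_direction(envw, c(0, 0), 0), Inf)
  expect_equal(distance_along_direction(envw, c(1, 0), 0), 1)
  expect_equal(distance_along_direction(envw, c(0, 1.5), pi / 2), 0.5)

  # oracle equivalence with dense sampling on a small instance
  env2 <- env_with_corals(c(0.6, 0.3, -0.4, 0.5), walls = FALSE)
  ang <- seq(-pi, pi, length.out = 73)
  for (a in ang) {
    d <- distance_along_direction(env2, c(0, 0), a)
    # brute force: march along the ray and find the first sample inside
    tt <- seq(0, 1.4, by = 1e-4)
    px <- 0 + tt * cos(a)
    pz <- 0 + tt * sin(a)
    inside <- rep(FALSE, length(tt))
    for (i in seq_len(nrow(env2$coral_centers))) {
      inside <- inside |
        ((px - env2$coral_centers[i, 1])^2 +
           (pz - env2$coral_centers[i, 2])^2 < env2$coral_radius^2)
    }
    if (any(inside)) {
      expect_equal(d, tt[which(inside)[1]], tolerance = 2e-4)
    } else {
      expect_identical(d, Inf)
    }
  }
})

test_that("affected bins cover the coral aperture with per-bin distances", {
  env <- env_with_corals(c(0.5, 0), walls = FALSE)
  ab <- affected_bins(env, c(0, 0), c(0.5, 0), n_bins = 24)
  # half aperture atan(0.15/0.5) = 16.7 deg spans bins at 0 and +/-15 deg
  expect_setequal(ab$bin, c(1L, 2L, 24L))
  expect_equal(ab$distance[ab$bin == 1], 0.35)
  # distances agree with the ray cast at each affected bin's direction
  for (k in seq_len(nrow(ab))) {
    a <- (ab$bin[k] - 1) * 2 * pi / 24
    expect_equal(ab$distance[k], distance_along_direction(env, c(0, 0), a))
  }
  # out of range -> empty
  far <- affected_bins(env, c(-1.2, 0), c(0.5, 0), n_bins = 24)
  expect_equal(nrow(far), 0)
  # tiny aperture centered on bin 1 -> exactly bin 1
  env2 <- env_with_corals(c(1.2, 0), walls = FALSE)
  ab2 <- affected_bins(env2, c(0, 0), c(1.2, 0), n_bins = 24)
  expect_identical(ab2$bin, 1L)
})

test_that("collision test uses strict center distance", {
  env <- env_with_corals(c(0.5, 0))
  expect_true(check_collision(env, c(0.5, 0)))
  expect_false(check_collision(env, c(0.5 + env$coral_radius, 0)))
  expect_true(check_collision(env, c(0.5 + env$coral_radius - 1e-9, 0)))
  env0 <- generate_environment(arena_config(n_corals = 0), seed = 1L)
  expect_false(check_collision(env0, c(0, 0)))
})

test_that("environment JSON serialization round-trips", {
  env <- generate_environment(arena_config(n_corals = 7), seed = 42L)
  path <- tempfile(fileext = ".json")
  write_environment(env, path)
  back <- read_environment(path)
  expect_equal(back$coral_centers, env$coral_centers)
  expect_equal(back$start, env$start)
  expect_equal(back$target, env$target)
  expect_equal(back$bounds, env$bounds)
  expect_equal(back$coral_radius, env$coral_radius)
  unlink(path)
})
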