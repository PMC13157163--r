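test_that("velocity composition and rotation are exact", {
  expect_equal(compose_velocity(0.5, 0), c(0.5, 0))
  expect_equal(compose_velocity(0.5, pi / 2), c(0, 0.5))
  expect_equal(compose_velocity(0, 1.3), c(0, 0))
  expect_error(compose_velocity(-0.1, 0))

  expect_equal(rotate(c(0.3, -0.4), 0), c(0.3, -0.4))
  expect_equal(rotate(c(1, 0), pi / 2), c(0, 1))
  set.seed(8)
  for (k in 1:20) {
    v <- stats::rnorm(2)
    th <- stats::runif(1, -pi, pi)
    expect_equal(sqrt(sum(rotate(v, th)^2)), sqrt(sum(v^2)),
                 tolerance = 1e-12)
  }
})

test_that("relative distance and the axis speed law match printed values", {
  expect_equal(relative_distance(0.4), 1)
  expect_equal(relative_distance(0.03), 0)
  expect_equal(relative_distance(0.215), 0.5)
  expect_equal(relative_distance(Inf), 1)
  expect_equal(relative_distance(0), 0)

  p <- control_params()
  expect_equal(axis_speed_update(0.5, Inf, p), 0.5)      # capped at v_max
  expect_equal(axis_speed_update(0.1, Inf, p), 0.4)      # 0.1 + 3 * 0.1
  expect_equal(axis_speed_update(0.3, 0.03, p), 0)       # full stop at eps
  # blocked: min((|v| + v_eps) * dhat, |v|), sign preserved
  expect_equal(axis_speed_update(0.3, 0.215, p), 0.175)
  expect_equal(axis_speed_update(-0.3, 0.215, p), -0.175)

  expect_equal(fold_potential(0.7), 0.5)
  expect_equal(fold_potential(-0.7), -0.5)
  expect_equal(fold_potential(0), 0)
  expect_equal(fold_potential(-0.3), -0.3)
})

test_that("steering smoothing blends 90% new with 10% old", {
  expect_equal(steer(0.4, 0.4), 0.4)
  expect_equal(steer(1, 0), 0.9)
  set.seed(9)
  for (k in 1:50) {
    tn <- stats::runif(1, -pi / 2, pi / 2)
    to <- stats::runif(1, -pi / 2, pi / 2)
    s <- steer(tn, to)
    expect_true(s >= -pi / 2 && s <= pi / 2)
  }
})

test_that("hydrostatic pressure bias switches regimes at the depth band", {
  b <- hp_bias(p_z = 0.5, g_z = 0.4, theta_hp = pi)
  expect_equal(b$regime, "horizontal")
  expect_equal(b$heading, pi)
  expect_equal(hp_bias(1, 1, 0)$regime, "horizontal")
  # 1 m above the target depth -> descend
  down <- hp_bias(p_z = 1, g_z = 0, theta_hp = 0)
  expect_equal(down$regime, "vertical")
  expect_equal(down$heading, -pi / 2)
  up <- hp_bias(p_z = -1, g_z = 0, theta_hp = 0)
  expect_equal(up$heading, pi / 2)
  # exactly at the band edge counts as vertical (strict inner inequality)
  expect_equal(hp_bias(0.2, 0, 0)$regime, "vertical")
})

test_that("error update tracks with tau2 and wraps heading errors", {
  expect_equal(error_update(0.7, 0.7), 0.7)
  s <- 0
  for (k in 1:100) s <- error_update(s, 1, tau2 = 0.1, dt = 0.001)
  expect_equal(s, 1 - exp(-1), tolerance = 1e-12)
  # shortest arc: 3.0 -> -3.0 moves through pi, not back through 0
  up <- error_update(3.0, -3.0, wrap = TRUE)
  expect_gt(up, 3.0)
  dn <- error_update(-3.0, 3.0, wrap = TRUE)
  expect_lt(dn, -3.0)
})

test_that("visual scene reports per-bin distances and target visibility", {
  # empty arena, agent at the center: walls beyond 1.4 m -> all clear
  env <- generate_environment(arena_config(n_corals = 0), seed = 1L,
                              start = c(0, 0), target = c(1.9, 1.9))
  sc <- visual_scene(env, list(p = c(0, 0), theta = 0))
  expect_length(sc$d, 24)
  expect_true(all(is.infinite(sc$d)))
  expect_false(sc$target_visible)

  # visibility radius is strict at 0.3 m
  env2 <- generate_environment(arena_config(n_corals = 0), seed = 1L,
                               start = c(0, 0), target = c(0.29, 0))
  expect_true(visual_scene(env2, list(p = c(0, 0), theta = 0))$target_visible)
  env3 <- generate_environment(arena_config(n_corals = 0), seed = 1L,
                               start = c(0, 0), target = c(0.31, 0))
  expect_false(visual_scene(env3, list(p = c(0, 0), theta = 0))$target_visible)

  # single coral dead ahead at 1 m -> d0 = 0.85, independent of heading
  envc <- env_with_corals(c(1, 0), walls = FALSE, start = c(0, 0))
  sc0 <- visual_scene(envc, list(p = c(0, 0), theta = 0))
  expect_equal(sc0$d0, 0.85)
  scr <- visual_scene(envc, list(p = c(1, -1), theta = pi / 2))
  expect_equal(scr$d0, 0.85)
})

test_that("BVC drive applies the tuning curve per bin", {
  envc <- env_with_corals(c(1, 0), walls = FALSE, start = c(0, 0))
  f <- bvc_tuning_curve(max_rate = 2, receptive_field = 1.4)
  sc <- visual_scene(envc, list(p = c(0, 0), theta = 0))
  dr <- bvc_drive(sc, f)
  expect_length(dr, 24)
  expect_equal(dr[1], 2 * (1 - 0.85 / 1.4))
  expect_true(all(dr[-1] == 0))   # clear bins map to zero

  # drive at contact is maximal
  sc2 <- visual_scene(envc, list(p = c(0.85, 0), theta = 0))
  expect_equal(bvc_drive(sc2, f)[1], 2)

  # drive is non-increasing as the coral recedes
  ds <- seq(0.2, 1.4, by = 0.1)
  drive1 <- vapply(ds, function(d) {
    e <- env_with_corals(c(d + 0.15, 0), walls = FALSE, start = c(0, 0))
    bvc_drive(visual_scene(e, list(p = c(0, 0), theta = 0)), f)[1]
  }, numeric(1))
  expect_true(all(diff(drive1) <= 1e-12))

  # per-bin tuning list variant
  fl <- replicate(24, f)
  expect_equal(bvc_drive(sc, fl), dr)
})

test_that("goal attractor activates only inside the visibility radius", {
  expect_equal(attractor_term(c(0, 0), c(0.5, 0)), c(0, 0))
  expect_equal(attractor_term(c(0.2, 0.2), c(0.2, 0.2)), c(0, 0))
  expect_equal(attractor_term(c(0, 0), c(0.1, 0.1)), c(0.1, 0.1))
})
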