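test_that("normalized time and distance match their printed anchors", {
  expect_equal(time_to_target_norm(2.5 / 0.5, 2.5), 0)   # t_reach = t_min
  expect_equal(time_to_target_norm(45, 2.5), 1)
  expect_equal(time_to_target_norm(25, 2.5), 0.5)        # t_min = 5
  expect_equal(time_to_target_norm(100, 2.5), 1)         # clipped

  expect_equal(distance_norm(2.5, 2.5), 0)
  expect_equal(distance_norm(22.5, 2.5), 1)
  expect_equal(distance_norm(12.5, 2.5), 0.5)
  expect_equal(distance_norm(1, 2.5), 0)                 # clipped below
})

test_that("collision rate counts samples strictly inside corals", {
  env <- env_with_corals(c(0, 0))
  x <- c(rep(0, 3), seq(0.5, 1.3, length.out = 9))
  traj <- cbind(x = x, z = rep(0, 12))
  expect_equal(collision_rate(traj, env), 3 / 12)
  expect_equal(collision_rate(traj[4:12, , drop = FALSE], env), 0)
  expect_equal(collision_rate(cbind(x = rep(0, 5), z = rep(0, 5)), env), 1)
  env0 <- generate_environment(arena_config(n_corals = 0), seed = 1L)
  expect_equal(collision_rate(traj, env0), 0)
})

test_that("total score folds failures and averages the three complements", {
  perfect <- list(reached = TRUE, time_norm = 0, dist_norm = 0,
                  collision_rate = 0)
  expect_equal(total_score(perfect), 1)
  failed <- list(reached = FALSE, time_norm = 0, dist_norm = 0,
                 collision_rate = 0)
  expect_equal(total_score(failed), 0)
  mixed <- list(reached = TRUE, time_norm = 0.25, dist_norm = 0.1,
                collision_rate = 0.05)
  expect_equal(total_score(mixed), 0.8666667, tolerance = 1e-6)
})

test_that("total score is bounded and monotone over random inputs", {
  set.seed(100)
  n <- 10000
  tn <- stats::runif(n)
  dn <- stats::runif(n)
  cr <- stats::runif(n)
  sc <- vapply(seq_len(n), function(i)
    total_score(list(reached = TRUE, time_norm = tn[i], dist_norm = dn[i],
                     collision_rate = cr[i])), numeric(1))
  expect_true(all(sc >= 0 & sc <= 1))
  # strictly decreasing in each component
  eps <- stats::runif(n, 0.001, 0.02)
  worse_t <- vapply(seq_len(n), function(i)
    total_score(list(reached = TRUE, time_norm = pmin(tn[i] + eps[i], 1),
                     dist_norm = dn[i], collision_rate = cr[i])), numeric(1))
  expect_true(all(worse_t <= sc))
  worse_c <- vapply(seq_len(n), function(i)
    total_score(list(reached = TRUE, time_norm = tn[i], dist_norm = dn[i],
                     collision_rate = pmin(cr[i] + eps[i], 1))), numeric(1))
  expect_true(all(worse_c <= sc))
})

test_that("path length and resampling are geometric", {
  sq <- cbind(x = c(0, 1, 1, 0, 0), z = c(0, 0, 1, 1, 0))
  expect_equal(path_length(sq), 4)
  expect_equal(path_length(sq[1, , drop = FALSE]), 0)
  rs <- resample_trajectory(sq, 9)
  expect_equal(dim(rs), c(9, 2))
  expect_equal(rs[1, ], c(0, 0))
  expect_equal(rs[9, ], c(0, 0))
  expect_equal(path_length(rs), 4, tolerance = 1e-9)
})

test_that("DTW distance is a pseudo-metric matching brute force", {
  a <- cbind(c(0, 1, 2), c(0, 0.5, 0))
  b <- cbind(c(0, 1.5, 2), c(0.2, -0.3, 0.1))
  expect_equal(dtw_distance(a, a), 0)
  expect_equal(dtw_distance(a, b), dtw_distance(b, a))
  expect_gte(dtw_distance(a, b), 0)
  # exhaustive warping-path enumeration on 3-point toys
  set.seed(14)
  for (k in 1:20) {
    p <- matrix(stats::rnorm(6), 3, 2)
    q <- matrix(stats::rnorm(6), 3, 2)
    expect_equal(dtw_distance(p, q, resample_n = 3), dtw_bruteforce(p, q),
                 tolerance = 1e-12)
  }
})

test_that("power analysis yields all unordered trajectory pairs", {
  set.seed(15)
  trajs <- lapply(1:10, function(i) matrix(stats::rnorm(20), 10, 2))
  pw <- power_analysis(trajs, resample_n = 50)
  expect_length(pw, 45)
  expect_length(power_analysis(trajs[1:2], resample_n = 50), 1)
  same <- lapply(1:4, function(i) trajs[[1]])
  expect_equal(power_analysis(same, resample_n = 50), rep(0, 6))
})

test_that("bootstrap success rate matches the binomial closed form", {
  b1 <- bootstrap_success(rep(1, 30))
  expect_equal(b1$mean, 1)
  expect_equal(b1$se, 0)
  b0 <- bootstrap_success(rep(0, 30))
  expect_equal(b0$mean, 0)
  expect_equal(b0$se, 0)
  bh <- bootstrap_success(rep(c(0, 1), 25), n_boot = 1000, seed = 2L)
  expect_equal(bh$se, sqrt(0.25 / 50), tolerance = 0.25)
  expect_equal(bh$mean, 0.5, tolerance = 0.05)
})

test_that("effect sizes match their closed forms", {
  a <- c(1, 2, 3, 4, 5)
  expect_equal(cohens_d(a, a), 0)
  b <- a + stats::sd(a)
  expect_equal(cohens_d(b, a), 1)
  expect_equal(cohens_d(a, b), -1)

  expect_equal(anova_eta2(list(a, a + 0, a + 0)), 0)
  expect_equal(anova_eta2(list(c(1, 1), c(2, 2), c(5, 5))), 1)
  # hand-computed sum of squares: SSb = 6, SSw = 6
  g <- list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5))
  expect_equal(anova_eta2(g), 0.5)
})

test_that("Welch and Student t-tests match the reference table", {
  a <- 1:5
  b <- c(2, 4, 6, 8, 10)
  # reference values from the closed forms:
  # means 3 and 6, variances 2.5 and 10
  # Welch: t = -3 / sqrt(2.5/5 + 10/5) = -1.897367, df = 5.882353
  w <- strategy_t_test(a, b)
  expect_equal(w$statistic, -1.897367, tolerance = 1e-6)
  expect_equal(w$df, 5.882353, tolerance = 1e-6)
  expect_equal(w$p_value, 0.107531, tolerance = 1e-5)
  expect_equal(w$estimate, -3)
  expect_true(w$conf_int[1] < -3 && w$conf_int[2] > -3)
  # Student: pooled sp^2 = 6.25, t identical for equal n, df = 8
  s <- strategy_t_test(a, b, var_equal = TRUE)
  expect_equal(s$statistic, -1.897367, tolerance = 1e-6)
  expect_equal(s$df, 8)
  expect_equal(s$p_value, 0.094350, tolerance = 1e-5)
  # paired: differences (-1, -2, -3, -4, -5), mean -3, sd sqrt(2.5)
  p <- strategy_t_test(a, b, paired = TRUE)
  expect_equal(p$statistic, -3 / sqrt(2.5 / 5), tolerance = 1e-9)
  expect_equal(p$df, 4)
})

test_that("Holm-Bonferroni steps down and bootstrap CIs are calibrated", {
  h <- holm_bonferroni(c(0.01, 0.04))
  expect_equal(h$p_adjusted, c(0.02, 0.04))
  expect_true(all(h$reject))
  expect_true(holm_bonferroni(0.04)$reject)
  expect_false(any(holm_bonferroni(rep(1, 4))$reject))
  h2 <- holm_bonferroni(c(0.03, 0.04))
  expect_equal(h2$p_adjusted, c(0.06, 0.06))
  expect_false(any(h2$reject))

  expect_equal(bootstrap_ci(mean, rep(2, 20), n = 200), c(2, 2))
  set.seed(99)
  x <- stats::rnorm(100, 5, 2)
  ci <- bootstrap_ci(mean, x, n = 10000, seed = 7L)
  expect_true(ci[1] < mean(x) && mean(x) < ci[2])
  analytic <- 2 * stats::qnorm(0.975) * stats::sd(x) / 10
  expect_equal(diff(ci), analytic, tolerance = 0.2)
})
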