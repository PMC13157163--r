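#' Normalized time to target
#'
#' Maps the reach time onto \[0, 1\]: 0 at the minimal possible time (the
#' straight-line distance at maximal speed) and 1 at the maximal simulation
#' time. Defined only for successful trials.
#'
#' @param t_reach Reach time, seconds.
#' @param straight_dist Straight-line start-to-target distance, metres.
#' @param v_max Maximal speed, m/s (default 0.5).
#' @param t_max Maximal simulation time, s (default 45).
#' @return Value in \[0, 1\] (clipped).
#' @export
time_to_target_norm <- function(t_reach, straight_dist, v_max = 0.5,
                                t_max = 45) {
  t_min <- straight_dist / v_max
  pmin(pmax((t_reach - t_min) / (t_max - t_min), 0), 1)
}

#' Normalized distance traveled
#'
#' 0 at the straight-line distance, 1 at the maximal possible path length
#' (`v_max * t_max`, 22.5 m under the defaults). Defined only for
#' successful trials.
#'
#' @param path_len Total path length, metres.
#' @param straight_dist Straight-line distance, metres.
#' @param v_max Maximal speed, m/s.
#' @param t_max Maximal simulation time, s.
#' @return Value in \[0, 1\] (clipped).
#' @export
distance_norm <- function(path_len, straight_dist, v_max = 0.5, t_max = 45) {
  dmax <- v_max * t_max
  pmin(pmax((path_len - straight_dist) / (dmax - straight_dist), 0), 1)
}

#' Collision rate of a trajectory
#'
#' Fraction of trajectory samples whose distance to any coral centre is
#' strictly smaller than the coral radius.
#'
#' @param traj Trajectory matrix with columns `x` and `z` (or a two-column
#'   matrix of positions).
#' @param env An `environment2d`.
#' @return Value in \[0, 1\].
#' @export
collision_rate <- function(traj, env) {
  pos <- traj_positions(traj)
  centers <- env$coral_centers
  if (nrow(centers) == 0 || nrow(pos) == 0) return(0)
  r2 <- env$coral_radius^2
  hit <- rep(FALSE, nrow(pos))
  for (i in seq_len(nrow(centers))) {
    dx <- pos[, 1] - centers[i, 1]
    dz <- pos[, 2] - centers[i, 2]
    hit <- hit | (dx * dx + dz * dz < r2)
  }
  mean(hit)
}

traj_positions <- function(traj) {
  if (is.matrix(traj) && all(c("x", "z") %in% colnames(traj))) {
    traj[, c("x", "z"), drop = FALSE]
  } else {
    as.matrix(traj)[, 1:2, drop = FALSE]
  }
}

#' Total trial score
#'
#' `reached * ((1 - time_norm) + (1 - dist_norm) + (1 - collision_rate)) / 3`.
#' Failed trials fold to 0.
#'
#' @param r A list with `reached`, `time_norm`, `dist_norm`,
#'   `collision_rate` (as in a `run_trial()` result).
#' @return Score in \[0, 1\].
#' @export
total_score <- function(r) {
  if (!isTRUE(as.logical(r$reached))) return(0)
  ((1 - r$time_norm) + (1 - r$dist_norm) + (1 - r$collision_rate)) / 3
}

#' Path length of a trajectory
#'
#' Sum of consecutive-sample Euclidean steps.
#'
#' @param traj Trajectory matrix (see [collision_rate()]).
#' @return Length in metres.
#' @export
path_length <- function(traj) {
  pos <- traj_positions(traj)
  if (nrow(pos) < 2) return(0)
  sum(sqrt(rowSums(diff(pos)^2)))
}

#' Resample ("stretch") a trajectory to a fixed length
#'
#' Linear interpolation of x and z over a uniform parameterization, so that
#' two trajectories can be compared sample-by-sample.
#'
#' @param traj Trajectory matrix.
#' @param n Target number of samples.
#' @return An `n` x 2 position matrix.
#' @export
resample_trajectory <- function(traj, n) {
  pos <- traj_positions(traj)
  m <- nrow(pos)
  if (m == 1) return(matrix(rep(pos, each = n), n, 2))
  u0 <- seq(0, 1, length.out = m)
  u1 <- seq(0, 1, length.out = n)
  cbind(stats::approx(u0, pos[, 1], u1)$y,
        stats::approx(u0, pos[, 2], u1)$y)
}

#' Dynamic time warping distance between two trajectories
#'
#' Standard DTW alignment cost under the Euclidean local distance: the
#' minimal sum of pairwise point distances over all monotone warping paths.
#' Trajectories are first resampled to a common length (the longer of the
#' two, or `resample_n` when given).
#'
#' @param trajA,trajB Trajectory matrices.
#' @param resample_n Common resampling length (default: the longer input).
#' @return Non-negative alignment cost.
#' @export
dtw_distance <- function(trajA, trajB, resample_n = NULL) {
  a <- traj_positions(trajA)
  b <- traj_positions(trajB)
  n <- if (is.null(resample_n)) max(nrow(a), nrow(b)) else resample_n
  a <- resample_trajectory(a, n)
  b <- resample_trajectory(b, n)
  na <- nrow(a); nb <- nrow(b)
  # local cost rows computed vectorized; DP row by row
  prev <- rep(Inf, nb + 1L)
  prev[1L] <- 0
  for (i in seq_len(na)) {
    ci <- sqrt((a[i, 1] - b[, 1])^2 + (a[i, 2] - b[, 2])^2)
    cur <- numeric(nb + 1L)
    cur[1L] <- Inf
    for (j in seq_len(nb)) {
      cur[j + 1L] <- ci[j] + min(prev[j], prev[j + 1L], cur[j])
    }
    prev <- cur
  }
  prev[nb + 1L]
}

#' Pairwise inter-trajectory distances
#'
#' DTW distance over all unordered pairs of the given trajectories (10
#' repeats yield 45 pairs); low values mean the strategy reproduces the
#' same route.
#'
#' @param trajs A list of trajectory matrices.
#' @param resample_n Common resampling length (default 500).
#' @return A numeric vector of `choose(n, 2)` distances.
#' @export
power_analysis <- function(trajs, resample_n = 500) {
  n <- length(trajs)
  rs <- lapply(trajs, resample_trajectory, n = resample_n)
  out <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      out <- c(out, dtw_distance(rs[[i]], rs[[j]], resample_n = resample_n))
    }
  }
  out
}

#' Bootstrap mean and standard error of a success rate
#'
#' @param flags Binary success flags.
#' @param n_boot Number of bootstrap resamples (default 100).
#' @param seed Integer seed.
#' @return List with `mean` and `se` of the bootstrap distribution.
#' @export
bootstrap_success <- function(flags, n_boot = 100, seed = 1L) {
  flags <- as.numeric(flags)
  with_seed(seed, {
    bs <- replicate(n_boot, mean(sample(flags, replace = TRUE)))
    list(mean = mean(bs), se = stats::sd(bs))
  })
}

#' Compare two strategies with a t-test
#'
#' Welch's unequal-variance t-test by default (strategy conditions rarely
#' share a variance), two-sided; set `paired = TRUE` for per-environment
#' paired designs and `var_equal = TRUE` for the Student variant.
#'
#' @param groupA,groupB Numeric vectors of per-trial values (e.g. total
#'   scores).
#' @param paired Paired test (default `FALSE`).
#' @param var_equal Assume equal variances (default `FALSE`, i.e. Welch).
#' @return A list with `statistic`, `df`, `p_value`, `estimate` (mean
#'   difference A - B) and `conf_int` (95 percent).
#' @export
strategy_t_test <- function(groupA, groupB, paired = FALSE,
                            var_equal = FALSE) {
  ht <- stats::t.test(groupA, groupB, paired = paired,
                      var.equal = var_equal)
  est <- if (paired) unname(ht$estimate)
         else unname(ht$estimate[1] - ht$estimate[2])
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, estimate = est,
       conf_int = unname(ht$conf.int))
}

#' Cohen's d effect size
#'
#' Paired-by-environment mean difference over the pooled within-group
#' standard deviation. Thresholds of 0.2 / 0.5 / 0.8 are conventionally
#' read as small / medium / large effects.
#'
#' @param groupA,groupB Numeric vectors (paired when of equal length).
#' @return Effect size d (positive when A > B).
#' @export
cohens_d <- function(groupA, groupB) {
  sp <- sqrt((stats::var(groupA) + stats::var(groupB)) / 2)
  if (sp == 0) return(0)
  (mean(groupA) - mean(groupB)) / sp
}

#' Partial eta squared from one-way ANOVA
#'
#' `SS_between / (SS_between + SS_within)` across the given groups.
#'
#' @param groups A list of numeric vectors, one per group.
#' @return Partial eta squared in \[0, 1\].
#' @export
anova_eta2 <- function(groups) {
  y <- unlist(groups, use.names = FALSE)
  f <- factor(rep(seq_along(groups), lengths(groups)))
  fit <- stats::aov(y ~ f)
  ss <- summary(fit)[[1]][["Sum Sq"]]
  if (sum(ss) == 0) return(0)
  ss[1] / sum(ss)
}

#' Holm-Bonferroni correction
#'
#' Step-down multiple-testing correction controlling the familywise error
#' rate.
#'
#' @param pvals Raw p-values.
#' @param alpha Familywise significance level (default 0.05).
#' @return A data frame with `p`, `p_adjusted` and `reject`.
#' @export
holm_bonferroni <- function(pvals, alpha = 0.05) {
  adj <- stats::p.adjust(pvals, method = "holm")
  data.frame(p = pvals, p_adjusted = adj, reject = adj <= alpha)
}

#' Bootstrap confidence interval
#'
#' Percentile bootstrap interval of an arbitrary statistic.
#'
#' @param stat_fn Function mapping a data vector to a scalar statistic.
#' @param data Numeric vector.
#' @param n Number of resamples (default 10000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return Length-2 interval (lower, upper).
#' @export
bootstrap_ci <- function(stat_fn, data, n = 10000, level = 0.95, seed = 1L) {
  with_seed(seed, {
    bs <- replicate(n, stat_fn(sample(data, replace = TRUE)))
    unname(stats::quantile(bs, c((1 - level) / 2, 1 - (1 - level) / 2)))
  })
}
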