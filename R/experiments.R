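#' Build a navigation strategy configuration
#'
#' The five strategy variants differ in the information available to the
#' agent and in the neural tuning:
#' * `null` -- no target information; the initial heading is drawn uniformly
#'   within +/-45 degrees of the true target bearing.
#' * `azimuth` -- the initial allocentric bearing to the target is given.
#' * `hp` -- the target's hydrostatic pressure (depth) is given, plus a
#'   fixed binary horizontal prior (left/right); tuned skew-normal
#'   distributions, rectified-linear BVC/HP neurons.
#' * `hp_max` -- as `hp` but LIF neurons everywhere, 400 spikes/s maximum
#'   rates and a 10x population.
#' * `hp_default` -- as `hp` but with generic simulator default tuning
#'   distributions.
#'
#' @param kind One of `"null"`, `"azimuth"`, `"hp"`, `"hp_max"`,
#'   `"hp_default"`.
#' @param noise_sigma Positional noise scale (default 0).
#' @param population_scale Multiplier on all population counts (default 1;
#'   desk-scale experiments use 0.2).
#' @param rate_scale Multiplier on maximum firing rates (default 1).
#' @param total_neurons Baseline neuron budget (default 10000).
#' @param base_spec Base [neuron_model_spec()].
#' @return An object of class `strategy_config`.
#' @export
make_strategy <- function(kind = c("null", "azimuth", "hp", "hp_max",
                                   "hp_default"),
                          noise_sigma = 0, population_scale = 1,
                          rate_scale = 1, total_neurons = 10000,
                          base_spec = neuron_model_spec()) {
  kind <- match.arg(kind)
  variant <- if (kind %in% c("hp_max", "hp_default")) kind else "hp"
  vt <- variant_tuning(variant, base_spec)
  budget <- allocate_populations(total_neurons)
  counts <- round(budget$counts * vt$population_multiplier *
                    population_scale)
  counts <- pmax(counts, 1L)
  structure(list(kind = kind, spec = vt$spec,
                 population_multiplier = vt$population_multiplier,
                 counts = counts, noise_sigma = noise_sigma,
                 population_scale = population_scale,
                 rate_scale = rate_scale,
                 total_neurons = total_neurons),
            class = "strategy_config")
}

#' Experiment plan
#'
#' Describes a batch: how many environments, repeats per environment, and
#' an optional sweep variable. The arena-size sweep scales the coral count
#' and the simulation duration proportionally with the arena side.
#'
#' @param n_environments Number of seeded environments.
#' @param repeats Repeats per environment and strategy.
#' @param sweep One of `"none"`, `"corals"`, `"arena"`, `"noise"`.
#' @param sweep_values Values of the sweep variable (defaults per sweep:
#'   corals `c(5, 10, 20, 30, 40)`, arena side `c(2, 4, 6, 8, 10)` m,
#'   noise `c(0, 0.1, 0.3)`).
#' @param n_corals Coral count for non-coral sweeps (default 25).
#' @param arena_side Arena side for non-arena sweeps (default 4 m).
#' @param seed Base seed; environment and trial seeds derive from it.
#' @return An object of class `experiment_plan`.
#' @export
experiment_plan <- function(n_environments = 20, repeats = 1,
                            sweep = c("none", "corals", "arena", "noise"),
                            sweep_values = NULL, n_corals = 25,
                            arena_side = 4, seed = 1L) {
  sweep <- match.arg(sweep)
  if (is.null(sweep_values))
    sweep_values <- switch(sweep,
                           none = NA_real_,
                           corals = c(5, 10, 20, 30, 40),
                           arena = c(2, 4, 6, 8, 10),
                           noise = c(0, 0.1, 0.3))
  structure(list(n_environments = n_environments, repeats = repeats,
                 sweep = sweep, sweep_values = sweep_values,
                 n_corals = n_corals, arena_side = arena_side,
                 seed = as.integer(seed)),
            class = "experiment_plan")
}

plan_config <- function(plan, value) {
  if (plan$sweep == "arena") {
    side <- value
    # coral count and duration scale with the arena side (4 m reference)
    arena_config(width = side, height = side,
                 n_corals = round(plan$n_corals * side / 4),
                 t_max = 45 * side / 4)
  } else if (plan$sweep == "corals") {
    arena_config(n_corals = value, width = plan$arena_side,
                 height = plan$arena_side)
  } else {
    arena_config(n_corals = plan$n_corals, width = plan$arena_side,
                 height = plan$arena_side)
  }
}

#' Run a batch of trials
#'
#' Runs `run_trial()` for every environment x strategy x repeat (x sweep
#' value) combination of the plan and returns one row per trial. Fully
#' seeded: environment `i` uses a seed derived from the plan seed and `i`,
#' and every trial seed derives from the environment seed, the strategy and
#' the repeat, so results are independent of execution order.
#'
#' @param plan An [experiment_plan()].
#' @param strategies A list of [make_strategy()] configurations (a single
#'   one is accepted).
#' @param params A [control_params()] (per-sweep copies inherit `t_max` and
#'   noise from the plan/strategy).
#' @param mode `"rate"` or `"spiking"`.
#' @param keep_trajectories Also return the trajectory list (default
#'   `FALSE`).
#' @return A data frame with columns env, strategy, repeat_ix, sweep_value,
#'   seed, reached, t_reach, time_norm, dist_norm, collision_rate,
#'   total_score; trajectories in `attr(, "trajectories")` when requested.
#' @export
run_batch <- function(plan, strategies, params = control_params(),
                      mode = "rate", keep_trajectories = FALSE) {
  if (inherits(strategies, "strategy_config")) strategies <- list(strategies)
  if (is.null(names(strategies)))
    names(strategies) <- vapply(strategies, `[[`, "", "kind")
  rows <- list()
  trajs <- list()
  for (vi in seq_along(plan$sweep_values)) {
    sv <- plan$sweep_values[vi]
    cfg <- plan_config(plan, sv)
    for (ei in seq_len(plan$n_environments)) {
      env_seed <- child_seed(plan$seed, vi, ei)
      env <- generate_environment(cfg, seed = env_seed)
      for (si in seq_along(strategies)) {
        strat <- strategies[[si]]
        if (plan$sweep == "noise") strat$noise_sigma <- sv
        par_i <- params
        par_i$t_max <- cfg$t_max
        par_i$noise_sigma <- strat$noise_sigma
        for (ri in seq_len(plan$repeats)) {
          trial_seed <- child_seed(env_seed, si, ri)
          out <- tryCatch(
            run_trial(env, strat, par_i, mode = mode, seed = trial_seed,
                      log = TRUE),
            error = function(e) list(trajectory = NULL,
                                     result = list(error = conditionMessage(e))))
          r <- out$result
          failed <- !is.null(r$error)
          rows[[length(rows) + 1L]] <- data.frame(
            env = ei, strategy = names(strategies)[si], repeat_ix = ri,
            sweep_value = sv, seed = trial_seed,
            reached = if (failed) FALSE else r$reached,
            t_reach = if (failed) NA_real_ else r$t_reach,
            time_norm = if (failed) NA_real_ else r$time_norm,
            dist_norm = if (failed) NA_real_ else r$dist_norm,
            collision_rate = if (failed) NA_real_ else r$collision_rate,
            total_score = if (failed) 0 else r$total_score)
          if (keep_trajectories)
            trajs[[length(trajs) + 1L]] <- out$trajectory
        }
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (keep_trajectories) attr(res, "trajectories") <- trajs
  res
}

#' Summarize a batch results table
#'
#' Per strategy (and sweep value): bootstrap success rate with SE, mean
#' normalized time/distance over successful trials, mean collision rate and
#' mean total score.
#'
#' @param results A [run_batch()] table.
#' @param seed Seed for the success-rate bootstrap.
#' @return A data frame, one row per strategy x sweep value.
#' @export
summarize_batch <- function(results, seed = 1L) {
  # paste keeps NA sweep values (plain batches) as a valid "NA" group;
  # interaction() would silently drop those rows
  key <- paste(results$strategy, results$sweep_value)
  parts <- split(results, key)
  out <- lapply(parts, function(d) {
    bs <- bootstrap_success(d$reached, seed = seed)
    data.frame(strategy = d$strategy[1], sweep_value = d$sweep_value[1],
               n = nrow(d), success_rate = mean(d$reached),
               success_se = bs$se,
               time_norm = mean(d$time_norm, na.rm = TRUE),
               dist_norm = mean(d$dist_norm, na.rm = TRUE),
               collision_rate = mean(d$collision_rate, na.rm = TRUE),
               total_score = mean(d$total_score))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare the A* planner baselines
#'
#' Generates `n_envs` environments with 20 corals, a fixed start at
#' (-1.8, -1.8) and a goal at (1.8, 1.8), runs the A* agent in global and
#' local modes on each, and reports per-mode results.
#'
#' @param n_envs Number of environments (default 20).
#' @param seed Base seed.
#' @param n_corals Corals per environment (default 20).
#' @return A data frame with one row per environment x mode.
#' @export
compare_astar <- function(n_envs = 20, seed = 1L, n_corals = 20) {
  cfg <- arena_config(n_corals = n_corals)
  rows <- list()
  for (ei in seq_len(n_envs)) {
    env <- generate_environment(cfg, seed = child_seed(seed, 7L, ei),
                                start = c(-1.8, -1.8), target = c(1.8, 1.8))
    for (mode in c("global", "local")) {
      out <- astar_run_agent(env, astar_config(mode = mode))
      r <- out$result
      rows[[length(rows) + 1L]] <- data.frame(
        env = ei, mode = mode, reached = r$reached,
        time_norm = r$time_norm, dist_norm = r$dist_norm,
        collision_rate = r$collision_rate, path_length = r$path_length,
        total_score = r$total_score)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Write batch results to CSV and a summary to JSON
#'
#' @param results A [run_batch()] table.
#' @param dir Output directory (created if needed).
#' @param seed Bootstrap seed for the summary.
#' @return The directory, invisibly.
#' @export
write_results <- function(results, dir, seed = 1L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(results, file.path(dir, "trials.csv"), row.names = FALSE)
  summ <- summarize_batch(results, seed = seed)
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Write a trial trajectory to CSV with a JSON metadata sidecar
#'
#' @param trajectory A trajectory matrix from [run_trial()].
#' @param path CSV file path; metadata goes to `<path>.json`.
#' @param meta Named list of metadata (strategy, seed, environment, ...).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path, meta = list()) {
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  if (length(meta))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' Read an experiment plan from a JSON or YAML file
#'
#' @param path File path (`.json`, `.yaml` or `.yml`).
#' @return An [experiment_plan()].
#' @export
read_plan <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML plans requires the yaml package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(experiment_plan, obj[intersect(names(obj),
    names(formals(experiment_plan)))])
}
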