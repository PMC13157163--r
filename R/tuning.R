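#' Skew-normal sampling specification
#'
#' Tuning parameters recorded in the goldfish telencephalon (peak firing
#' rates, receptive-field sizes) follow right-skewed unimodal distributions;
#' they are modelled here as skew-normals with hard clip bounds.
#'
#' @param location,scale,shape Skew-normal parameters (`scale > 0`).
#' @param clip_low,clip_high Samples are clipped into this interval.
#' @return An object of class `skew_normal_spec`.
#' @export
skew_normal_spec <- function(location, scale, shape,
                             clip_low = -Inf, clip_high = Inf) {
  stopifnot(scale > 0, clip_low < clip_high)
  structure(list(location = location, scale = scale, shape = shape,
                 clip_low = clip_low, clip_high = clip_high),
            class = "skew_normal_spec")
}

#' Sample from a skew-normal distribution
#'
#' Uses the two-normal representation: with `delta = shape / sqrt(1 +
#' shape^2)`, `Z = delta * |U0| + sqrt(1 - delta^2) * U1` is standard
#' skew-normal for independent standard normals `U0`, `U1`.
#'
#' @param n Number of samples.
#' @param spec A [skew_normal_spec()].
#' @param clip Apply the spec's clip bounds (default `TRUE`).
#' @return Numeric vector of length `n`.
#' @export
rskewnorm <- function(n, spec, clip = TRUE) {
  stopifnot(inherits(spec, "skew_normal_spec"), n >= 0)
  if (n == 0) return(numeric(0))
  delta <- spec$shape / sqrt(1 + spec$shape^2)
  u0 <- stats::rnorm(n)
  u1 <- stats::rnorm(n)
  z <- delta * abs(u0) + sqrt(1 - delta^2) * u1
  x <- spec$location + spec$scale * z
  if (clip) x <- pmin(pmax(x, spec$clip_low), spec$clip_high)
  x
}

# Analytic mean / sd of the (unclipped) skew-normal; used by tests.
skewnorm_moments <- function(spec) {
  delta <- spec$shape / sqrt(1 + spec$shape^2)
  mu <- spec$location + spec$scale * delta * sqrt(2 / pi)
  sd <- spec$scale * sqrt(1 - 2 * delta^2 / pi)
  c(mean = mu, sd = sd)
}

#' Default tuning specifications
#'
#' Peak-rate and receptive-field distributions for BVC and HP populations.
#' The published summaries constrain the observed range (0.1--4 spikes/s
#' peak rates, receptive fields up to 1.4 m) and the right-skewed shape;
#' the skew-normal parameters here were chosen to reproduce those
#' qualitative summaries and are fully configurable.
#'
#' @param kind One of `"bvc_rate"`, `"bvc_rf"`, `"hp_rate"`.
#' @return A [skew_normal_spec()].
#' @export
default_tuning_spec <- function(kind = c("bvc_rate", "bvc_rf", "hp_rate")) {
  kind <- match.arg(kind)
  switch(kind,
    bvc_rate = skew_normal_spec(0.5, 1.2, 4, clip_low = 0.1, clip_high = 4),
    bvc_rf   = skew_normal_spec(0.25, 0.45, 3, clip_low = 0.01,
                                clip_high = 1.4),
    hp_rate  = skew_normal_spec(0.5, 1.2, 4, clip_low = 0.1, clip_high = 4)
  )
}

#' Neuron model specification
#'
#' @param kind `"lif"` (leaky integrate-and-fire) or `"relu"` (spiking
#'   rectified linear, whose approximately linear tuning matches measured
#'   BVC response profiles).
#' @param max_rate_dist A [skew_normal_spec()] for peak rates, or a length-2
#'   numeric range for uniform sampling.
#' @param intercept_dist A [skew_normal_spec()] for receptive-field
#'   intercepts, or `"default"` for standard-normal intercepts truncated to
#'   (-1, 1).
#' @param tau_rc Membrane time constant in seconds (LIF; default 0.02).
#' @param tau_ref Refractory period in seconds (LIF; default 0.002).
#' @return An object of class `neuron_model_spec`.
#' @export
neuron_model_spec <- function(kind = c("relu", "lif"),
                              max_rate_dist = default_tuning_spec("bvc_rate"),
                              intercept_dist = default_tuning_spec("bvc_rf"),
                              tau_rc = 0.02, tau_ref = 0.002) {
  kind <- match.arg(kind)
  structure(list(kind = kind, max_rate_dist = max_rate_dist,
                 intercept_dist = intercept_dist,
                 tau_rc = tau_rc, tau_ref = tau_ref),
            class = "neuron_model_spec")
}

#' Allocate the neural population budget
#'
#' Splits a total neuron budget across cell types following the recorded
#' proportions: the BVC share equals the recorded fraction (35 of 196
#' units), kinematic populations (speed, head direction, velocity) and HP
#' cells get a fixed per-type count, and the remainder goes to the
#' position/step-size ensembles.
#'
#' @param total Total neuron count (default 10000).
#' @param recorded_bvc Length-2 recorded counts `(bvc, total)` fixing the
#'   BVC fraction (default `c(35, 196)`).
#' @param per_kinematic Neurons per kinematic/HP population (default 1500).
#' @return An object of class `population_budget` with `total`, `fractions`
#'   and `counts`.
#' @export
allocate_populations <- function(total = 10000, recorded_bvc = c(35, 196),
                                 per_kinematic = 1500) {
  stopifnot(total > 0, length(recorded_bvc) == 2, recorded_bvc[2] > 0)
  if (total < recorded_bvc[2])
    warning("total below the recorded sample size; some counts may be 0")
  frac_bvc <- recorded_bvc[1] / recorded_bvc[2]
  n_bvc <- floor(total * frac_bvc)
  per_k <- min(per_kinematic, floor(total / 6))
  counts <- c(bvc = n_bvc, hp = per_k, speed = per_k,
              head_direction = per_k, velocity = per_k)
  counts <- pmax(counts, 0)
  counts <- c(counts, position = max(total - sum(counts), 0))
  structure(list(total = as.integer(total),
                 fractions = counts / total,
                 counts = as.integer(counts) |> stats::setNames(names(counts))),
            class = "population_budget")
}

#' Sample BVC tuning parameters
#'
#' Draws peak firing rates (clipped to the observed 0.1--4 spikes/s range)
#' and receptive-field sizes (clipped to (0, 1.4\] m) from the spec's
#' skew-normal distributions.
#'
#' @param n Number of neurons.
#' @param spec A [neuron_model_spec()].
#' @param seed Integer seed.
#' @return List with `max_rates` (spikes/s) and `receptive_fields` (m).
#' @export
sample_bvc_tuning <- function(n, spec = neuron_model_spec(), seed = 1L) {
  stopifnot(n >= 0)
  with_seed(seed, {
    max_rates <- sample_rates(n, spec$max_rate_dist)
    rf <- sample_intercept_domain(n, spec$intercept_dist, domain = 1.4)
    list(max_rates = max_rates, receptive_fields = rf)
  })
}

#' Sample HP-cell tuning parameters
#'
#' Same procedure as [sample_bvc_tuning()], with the tuning-intercept
#' domain equal to the arena's vertical extent (depth).
#'
#' @param n Number of neurons.
#' @param spec A [neuron_model_spec()].
#' @param seed Integer seed.
#' @param depth_range Depth domain in metres (default 4).
#' @return List with `max_rates` (spikes/s) and `depth_intercepts` (m).
#' @export
sample_hp_tuning <- function(n, spec = neuron_model_spec(
                               max_rate_dist = default_tuning_spec("hp_rate")),
                             seed = 1L, depth_range = 4) {
  stopifnot(n >= 0)
  with_seed(seed, {
    max_rates <- sample_rates(n, spec$max_rate_dist)
    di <- sample_intercept_domain(n, spec$intercept_dist,
                                  domain = depth_range)
    list(max_rates = max_rates, depth_intercepts = di)
  })
}

sample_rates <- function(n, dist) {
  if (inherits(dist, "skew_normal_spec")) {
    rskewnorm(n, dist)
  } else if (is.numeric(dist) && length(dist) == 2) {
    stats::runif(n, dist[1], dist[2])
  } else stop("unsupported max-rate distribution")
}

sample_intercept_domain <- function(n, dist, domain) {
  if (inherits(dist, "skew_normal_spec")) {
    # spec is expressed on [0, 1.4] m; rescale to the requested domain
    x <- rskewnorm(n, dist)
    x * (domain / 1.4)
  } else if (identical(dist, "default")) {
    # standard-normal intercepts truncated to (-1, 1), mapped onto the
    # domain (0, domain]
    x <- stats::rnorm(n)
    while (any(abs(x) >= 1)) x[abs(x) >= 1] <- stats::rnorm(sum(abs(x) >= 1))
    (x + 1) / 2 * domain
  } else stop("unsupported intercept distribution")
}

#' Strategy tuning variants
#'
#' Returns the neuron-model specification for a named model variant:
#' * `hp` -- the base, electrophysiologically tuned spec (rectified-linear
#'   BVC/HP, skew-normal rate and receptive-field distributions);
#' * `hp_max` -- LIF neurons everywhere, maximum firing rate 400 spikes/s,
#'   and a 10x population multiplier;
#' * `hp_default` -- same counts as `hp`, but generic simulator defaults:
#'   standard-normal intercepts truncated to (-1, 1) and uniform maximum
#'   rates in 200--400 spikes/s.
#'
#' @param variant One of `"hp"`, `"hp_max"`, `"hp_default"`.
#' @param base A [neuron_model_spec()] used as the starting point.
#' @return A list with `spec` (the possibly modified `neuron_model_spec`)
#'   and `population_multiplier`.
#' @export
variant_tuning <- function(variant = c("hp", "hp_max", "hp_default"),
                           base = neuron_model_spec()) {
  variant <- match.arg(variant)
  switch(variant,
    hp = list(spec = base, population_multiplier = 1),
    hp_max = list(
      spec = neuron_model_spec(kind = "lif",
                               max_rate_dist = c(390, 400),
                               intercept_dist = "default",
                               tau_rc = base$tau_rc, tau_ref = base$tau_ref),
      population_multiplier = 10),
    hp_default = list(
      spec = neuron_model_spec(kind = base$kind,
                               max_rate_dist = c(200, 400),
                               intercept_dist = "default",
                               tau_rc = base$tau_rc, tau_ref = base$tau_ref),
      population_multiplier = 1)
  )
}

#' BVC distance tuning curve
#'
#' Builds the boundary-distance response function of one BVC channel:
#' firing is maximal at boundary contact and decreases approximately
#' linearly to zero at the edge of the receptive field (the rectified-linear
#' profile observed in the recordings).
#'
#' @param max_rate Peak firing rate, spikes/s.
#' @param receptive_field Receptive-field size in metres.
#' @return A function `f(d)` mapping distance (m, `Inf` = clear) to firing
#'   rate (spikes/s).
#' @export
bvc_tuning_curve <- function(max_rate, receptive_field) {
  force(max_rate); force(receptive_field)
  function(d) {
    out <- max_rate * pmax(1 - d / receptive_field, 0)
    out[!is.finite(d)] <- 0
    out
  }
}
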