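#' Create a neural ensemble
#'
#' An ensemble is a population of neurons jointly representing a
#' low-dimensional variable x (|x| <= radius). Each neuron i has a unit
#' encoder e_i, a gain and a bias chosen so that its firing rate is zero at
#' its intercept and `max_rate` at full encoder alignment (x = radius * e_i).
#'
#' @param n_neurons Number of neurons.
#' @param dim Represented dimensionality (1 or 2 here).
#' @param max_rates Per-neuron maximum rates (spikes/s); recycled.
#' @param intercepts Per-neuron intercepts in \[-1, 1); recycled.
#' @param neuron_kind `"lif"` or `"relu"`.
#' @param radius Representational radius (default 1).
#' @param tau_rc,tau_ref LIF membrane and refractory time constants (s).
#' @param seed Seed for encoder sampling.
#' @return An object of class `nef_ensemble`.
#' @export
nef_ensemble <- function(n_neurons, dim = 1, max_rates = c(200, 400),
                         intercepts = NULL, neuron_kind = c("lif", "relu"),
                         radius = 1, tau_rc = 0.02, tau_ref = 0.002,
                         seed = 1L) {
  neuron_kind <- match.arg(neuron_kind)
  stopifnot(n_neurons >= 1, dim >= 1)
  with_seed(seed, {
    if (length(max_rates) == 2 && n_neurons != 2)
      max_rates <- stats::runif(n_neurons, max_rates[1], max_rates[2])
    max_rates <- rep_len(max_rates, n_neurons)
    if (is.null(intercepts))
      intercepts <- stats::runif(n_neurons, -1, 0.95)
    intercepts <- rep_len(intercepts, n_neurons)
    intercepts <- pmin(pmax(intercepts, -1), 0.999)
    if (dim == 1) {
      encoders <- matrix(sample(c(-1, 1), n_neurons, replace = TRUE),
                         ncol = 1)
    } else {
      encoders <- matrix(stats::rnorm(n_neurons * dim), ncol = dim)
      encoders <- encoders / sqrt(rowSums(encoders^2))
    }
    gb <- gain_bias(neuron_kind, max_rates, intercepts, tau_rc, tau_ref)
    structure(
      list(n_neurons = as.integer(n_neurons), dim = as.integer(dim),
           encoders = encoders, gains = gb$gain, biases = gb$bias,
           max_rates = max_rates, intercepts = intercepts,
           neuron_kind = neuron_kind, radius = radius,
           tau_rc = tau_rc, tau_ref = tau_ref, seed = as.integer(seed)),
      class = "nef_ensemble")
  })
}

# Solve per-neuron gain/bias from (max_rate, intercept). Currents are kept
# in "drive" space, the suprathreshold current J - J_threshold: for relu the
# drive is the rate itself; for LIF the drive is J - 1. Working with the
# drive rather than J avoids catastrophic cancellation at low maximum rates
# (a LIF neuron firing at 1 spike/s has J_max - 1 ~ 5e-15, far below the
# relative resolution of 1 + x in double precision), which would silently
# silence neurons whose operating range lies within ~1e-16 of threshold.
gain_bias <- function(kind, max_rates, intercepts, tau_rc, tau_ref) {
  if (kind == "relu") {
    gain <- max_rates / (1 - intercepts)
  } else {
    # LIF: drive = 0 at the intercept; rate(drive_max) = max_rate at x = 1;
    # drive_max = J_max - 1 = 1/(exp(z) - 1) with z = (1/rate - tau_ref)/tau_rc
    drive_max <- 1 / expm1((1 / max_rates - tau_ref) / tau_rc)
    gain <- drive_max / (1 - intercepts)
  }
  list(gain = gain, bias = -gain * intercepts)
}

# Per-neuron input current for represented value(s) x (rows = eval points).
ens_current <- function(e, x) {
  x <- as_matrix_rows(x, e$dim)
  (x %*% t(e$encoders)) / e$radius * rep(e$gains, each = nrow(x)) +
    rep(e$biases, each = nrow(x))
}

#' Rate-mode tuning curves
#'
#' Instantaneous firing rates of every neuron in the ensemble for one or
#' more represented values.
#'
#' @param e An [nef_ensemble()].
#' @param x A represented value (length `dim`) or a matrix with one value
#'   per row.
#' @return A matrix of rates, one row per evaluation point.
#' @export
nef_rates <- function(e, x) {
  j <- ens_current(e, x)   # drive: relu rate, or LIF suprathreshold current
  if (e$neuron_kind == "relu") {
    pmax(j, 0)
  } else {
    r <- matrix(0, nrow(j), ncol(j))
    above <- j > 0
    r[above] <- 1 / (e$tau_ref + e$tau_rc * log1p(1 / j[above]))
    r
  }
}

as_matrix_rows <- function(x, dim) {
  if (is.matrix(x)) x else matrix(x, ncol = dim, byrow = TRUE)
}

#' Compute least-squares decoders
#'
#' Solves for decoders d minimizing ||A d - f(X)||^2 + m * sigma^2 ||d||^2
#' over evaluation points X sampled in the represented domain, where A are
#' the tuning-curve rates and sigma = `regularization` x the maximum rate
#' (never singular for positive regularization).
#'
#' @param e An [nef_ensemble()].
#' @param f Function of the represented variable (vectorized over rows);
#'   default identity.
#' @param regularization Relative regularization (default 0.1).
#' @param n_eval Number of evaluation points (default 500).
#' @param seed Seed for evaluation-point sampling.
#' @return A decoder matrix (`n_neurons` x output dim).
#' @export
compute_decoders <- function(e, f = identity, regularization = 0.1,
                             n_eval = 500, seed = 1L) {
  stopifnot(e$n_neurons >= 1, regularization > 0)
  X <- eval_points(e, n_eval, seed)
  A <- nef_rates(e, X)
  targets <- f(X)
  if (!is.matrix(targets)) targets <- matrix(targets, nrow = nrow(X))
  sigma <- regularization * max(A)
  if (sigma <= 0) sigma <- regularization  # silent population edge case
  G <- crossprod(A) + diag(nrow(X) * sigma^2, ncol(A))
  solve(G, crossprod(A, targets))
}

eval_points <- function(e, n_eval, seed) {
  with_seed(seed, {
    if (e$dim == 1) {
      matrix(seq(-e$radius, e$radius, length.out = n_eval), ncol = 1)
    } else {
      # uniform in the ball of the representational radius
      z <- matrix(stats::rnorm(n_eval * e$dim), ncol = e$dim)
      z <- z / sqrt(rowSums(z^2))
      r <- e$radius * stats::runif(n_eval)^(1 / e$dim)
      z * r
    }
  })
}

#' Decode a represented value in rate mode
#'
#' @param e An [nef_ensemble()].
#' @param x Represented value(s).
#' @param decoders Decoder matrix from [compute_decoders()].
#' @return Decoded output (matrix, one row per evaluation point).
#' @export
nef_decode <- function(e, x, decoders) {
  nef_rates(e, x) %*% decoders
}

#' First-order synaptic low-pass filter step
#'
#' Exact discrete update of the synaptic filter
#' `state <- state + (1 - exp(-dt / tau)) * (input - state)`.
#'
#' @param state Current filter state (scalar or vector).
#' @param input Input value (same shape).
#' @param tau Time constant in seconds (> 0).
#' @param dt Time step in seconds (> 0).
#' @return Updated state.
#' @export
lowpass_step <- function(state, input, tau, dt) {
  stopifnot(tau > 0, dt > 0)
  state + (1 - exp(-dt / tau)) * (input - state)
}

#' Neural integrator step
#'
#' One step of the recurrent integrator implementing dp/dt = v: identity
#' feedback through a synapse of time constant `tau2` with the input scaled
#' by `tau2`. With exact decoders the discrete update is
#' `p + tau2 * (1 - exp(-dt/tau2)) * v`, which approaches `p + v * dt` for
#' `dt << tau2`.
#'
#' @param pos_state Current position estimate (scalar or vector).
#' @param velocity_input Velocity input (same shape), m/s.
#' @param tau2 Synaptic time constant in seconds (> 0).
#' @param dt Time step in seconds.
#' @return Updated position state.
#' @export
integrator_step <- function(pos_state, velocity_input, tau2, dt) {
  stopifnot(tau2 > 0, dt > 0)
  a <- 1 - exp(-dt / tau2)
  # lowpass toward the recurrent target (pos + tau2 * v)
  pos_state + a * tau2 * velocity_input
}

#' Winner-take-all action selection
#'
#' Functional stand-in for the basal-ganglia/thalamus selection circuit:
#' utilities are (optionally) low-pass filtered against a previous utility
#' state, and the index of the maximal filtered utility is returned, with a
#' deterministic tie-break to the lowest index.
#'
#' @param utilities Non-empty numeric vector.
#' @param tau Smoothing time constant in seconds; `0` disables filtering.
#' @param state Previous filtered utilities (same length), or `NULL`.
#' @param dt Time step used with `tau` (default 0.001).
#' @return A list with `index` (1-based winner), `action` (one-hot vector)
#'   and `state` (filtered utilities to carry to the next call).
#' @export
winner_take_all <- function(utilities, tau = 0, state = NULL, dt = 0.001) {
  if (length(utilities) == 0) stop("winner_take_all: empty utilities")
  filt <- if (tau > 0 && !is.null(state)) {
    lowpass_step(state, utilities, tau, dt)
  } else utilities
  idx <- which.max(filt)  # which.max breaks ties toward the lowest index
  action <- numeric(length(filt))
  action[idx] <- 1
  list(index = idx, action = action, state = filt)
}

# ---- spiking dynamics -----------------------------------------------------

# Initialize per-neuron spiking state. For LIF the membrane state is stored
# as the distance-to-threshold w = 1 - v (1 at rest, spike when w <= 0),
# which stays numerically exact for drives arbitrarily close to threshold.
# Initial phases are drawn from the caller's RNG stream: rest-synchronized
# neurons would all stay silent for up to a full interspike interval (~1 s
# at the low rates used here), a population-wide dead time with no
# biological counterpart. When the initial represented value `x` is known,
# LIF phases are drawn uniformly in *time* along each neuron's firing cycle
# (the stationary phase distribution); otherwise uniformly in voltage.
ens_spike_state <- function(e, x = NULL) {
  n <- e$n_neurons
  ref <- numeric(n)
  if (e$neuron_kind == "lif" && !is.null(x)) {
    j <- drop(ens_current(e, x))
    w <- pmin(pmax(-j, 0), 1)          # subthreshold equilibrium w = -drive
    act <- j > 0
    if (any(act)) {
      ja <- j[act]
      t_int <- e$tau_rc * log1p(1 / ja)        # integration time per cycle
      u <- stats::runif(sum(act)) * (e$tau_ref + t_int)
      in_ref <- u < e$tau_ref
      wa <- numeric(sum(act))
      ra <- numeric(sum(act))
      ra[in_ref] <- e$tau_ref - u[in_ref]
      wa[in_ref] <- 1
      t0 <- u[!in_ref] - e$tau_ref
      wa[!in_ref] <- (1 + ja[!in_ref]) * exp(-t0 / e$tau_rc) - ja[!in_ref]
      w[act] <- wa
      ref[act] <- ra
    }
    return(list(voltage = w, refractory = ref))
  }
  list(voltage = stats::runif(n), refractory = ref)
}

# Advance the spiking neurons by dt given represented input x.
# Returns list(spikes = spike vector scaled to 1/dt, state = new state).
ens_spike_step <- function(e, x, state, dt) {
  j <- drop(ens_current(e, x))   # drive (see gain_bias)
  v <- state$voltage
  if (e$neuron_kind == "relu") {
    # spiking rectified linear: accumulate rate * dt, emit on crossing 1
    v <- v + pmax(j, 0) * dt
    spikes <- floor(v)
    v <- v - spikes
  } else {
    # LIF in threshold-distance form: dv/dt = (J - v)/tau_rc with J = 1 +
    # drive becomes dw/dt = -(drive + w)/tau_rc for w = 1 - v, integrated
    # exactly: w(t) = -j + (j + w0) exp(-t/tau_rc) (the same solution the
    # stationary-phase initializer assumes)
    ref <- state$refractory
    dtv <- pmax(dt - ref, 0)           # time actually integrating
    w0 <- v
    v <- -j + (j + w0) * exp(-dtv / e$tau_rc)
    v[v > 1] <- 1                      # membrane clamped at rest (v >= 0)
    spiked <- v < 0
    spikes <- as.numeric(spiked)
    ref <- pmax(ref - dt, 0)
    if (any(spiked)) {
      # interpolate the threshold-crossing time within the step and start
      # the refractory there, so the mean interspike interval is unbiased
      # (a full-dt reset lengthens every cycle by up to dt, an 18% rate
      # deficit at 400 spikes/s with dt = 1 ms)
      t_cross <- e$tau_rc * log((w0[spiked] + j[spiked]) / j[spiked])
      over <- dtv[spiked] - t_cross    # time already past the crossing
      ref[spiked] <- pmax(e$tau_ref - over, 0)
      v[spiked] <- 1                   # reset to rest
    }
    state$refractory <- ref
  }
  state$voltage <- v
  list(spikes = spikes / dt, state = state)
}

# ---- minimal network + simulator -----------------------------------------

#' Build a minimal NEF network
#'
#' A lightweight container for nodes (external signals), ensembles,
#' connections (with optional decoded functions and synaptic filters) and
#' probes, simulated with [nef_simulate()]. Connections into an ensemble
#' set its represented input; connections out of an ensemble decode it
#' (rate mode) or filter its spike train through the decoders (spiking
#' mode).
#'
#' @return An object of class `nef_network`; add components with
#'   [add_node()], [add_ensemble()], [add_connection()], [add_probe()].
#' @export
nef_network <- function() {
  structure(list(nodes = list(), ensembles = list(), connections = list(),
                 probes = list()),
            class = "nef_network")
}

#' @rdname nef_network
#' @param net An `nef_network`.
#' @param name Component name.
#' @param fn For nodes: `function(t)` returning the node output.
#' @export
add_node <- function(net, name, fn) {
  net$nodes[[name]] <- fn
  net
}

#' @rdname nef_network
#' @param ensemble An [nef_ensemble()].
#' @export
add_ensemble <- function(net, name, ensemble) {
  net$ensembles[[name]] <- ensemble
  net
}

#' @rdname nef_network
#' @param source,target Component names (`"node:x"` / `"ens:x"` prefixes are
#'   not needed; names must be unique across nodes and ensembles).
#' @param f Function applied to the source's represented value (default
#'   identity), realized through decoders when the source is an ensemble.
#' @param synapse Synaptic time constant in seconds (0 = none).
#' @export
add_connection <- function(net, source, target, f = identity,
                           synapse = 0.005) {
  net$connections[[length(net$connections) + 1L]] <-
    list(source = source, target = target, f = f, synapse = synapse)
  net
}

#' @rdname nef_network
#' @param probe Name of the component whose (decoded) output to record.
#' @export
add_probe <- function(net, name, probe) {
  net$probes[[name]] <- probe
  net
}

#' Simulate a minimal NEF network
#'
#' Fixed-step simulation. In `"rate"` mode every ensemble outputs its
#' decoded rate response (deterministic); in `"spiking"` mode neurons emit
#' discrete spikes and decoded outputs are synaptically filtered spike
#' trains (reproducible under a fixed seed).
#'
#' @param net An [nef_network()].
#' @param duration Simulation length in seconds (> 0 for a non-empty run).
#' @param dt Time step in seconds (default 0.001).
#' @param mode `"rate"` or `"spiking"`.
#' @param seed Integer seed (spiking mode ensemble construction noise).
#' @return A list of probed time series: each a matrix with a `time` column
#'   followed by the probed channels.
#' @export
nef_simulate <- function(net, duration, dt = 0.001,
                         mode = c("rate", "spiking"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(dt > 0, duration >= 0)
  comp_names <- c(names(net$nodes), names(net$ensembles))
  for (pr in net$probes)
    if (!pr %in% comp_names) stop("unconnected probe: ", pr)
  n_steps <- floor(duration / dt + 1e-9)
  probes_out <- lapply(net$probes, function(p) NULL)

  # precompute decoders for connections out of ensembles
  decs <- lapply(net$connections, function(cn) {
    if (cn$source %in% names(net$ensembles))
      compute_decoders(net$ensembles[[cn$source]], cn$f, seed = seed)
    else NULL
  })

  # state: represented input per ensemble, filter states per connection,
  # spiking state per ensemble, last output per component
  ens_in <- lapply(net$ensembles, function(e) numeric(e$dim))
  filt <- vector("list", length(net$connections))
  outputs <- stats::setNames(vector("list", length(comp_names)), comp_names)

  if (n_steps == 0) {
    return(lapply(net$probes, function(p)
      matrix(numeric(0), 0, 2, dimnames = list(NULL, c("time", "value")))))
  }

  with_seed(seed, {
    spike_states <- lapply(net$ensembles, ens_spike_state)
    for (k in seq_len(n_steps)) {
      t <- k * dt
      # 1. node outputs
      for (nm in names(net$nodes)) outputs[[nm]] <- net$nodes[[nm]](t)
      # 2. ensemble outputs from their current represented input
      for (nm in names(net$ensembles)) {
        e <- net$ensembles[[nm]]
        if (mode == "rate") {
          outputs[[nm]] <- ens_in[[nm]]   # decoded via connection decoders
        } else {
          st <- ens_spike_step(e, ens_in[[nm]], spike_states[[nm]], dt)
          spike_states[[nm]] <- st$state
          outputs[[nm]] <- st$spikes      # decoded below per connection
        }
      }
      # 3. propagate connections, accumulate into ensemble inputs
      new_in <- lapply(net$ensembles, function(e) numeric(e$dim))
      conn_out <- stats::setNames(vector("list", length(comp_names)),
                                  comp_names)
      for (ci in seq_along(net$connections)) {
        cn <- net$connections[[ci]]
        src <- outputs[[cn$source]]
        val <- if (!is.null(decs[[ci]])) {
          e <- net$ensembles[[cn$source]]
          if (mode == "rate") {
            drop(nef_decode(e, ens_in[[cn$source]], decs[[ci]]))
          } else {
            drop(matrix(src, 1) %*% decs[[ci]])
          }
        } else {
          cn$f(src)
        }
        if (cn$synapse > 0) {
          if (is.null(filt[[ci]])) filt[[ci]] <- val * 0
          filt[[ci]] <- lowpass_step(filt[[ci]], val, cn$synapse, dt)
          val <- filt[[ci]]
        }
        if (cn$target %in% names(net$ensembles)) {
          new_in[[cn$target]] <- new_in[[cn$target]] + val
        }
        conn_out[[cn$target]] <- val
      }
      ens_in <- new_in
      # 4. record probes (decoded filtered value arriving at / leaving a
      # component: for ensembles, the filtered decoded output of the first
      # outgoing connection; for nodes, the node output)
      for (pn in names(net$probes)) {
        comp <- net$probes[[pn]]
        val <- if (comp %in% names(net$nodes)) {
          outputs[[comp]]
        } else {
          ci <- which(vapply(net$connections, function(cn)
            cn$source == comp, logical(1)))[1]
          if (is.na(ci)) {
            ens_in[[comp]]
          } else if (!is.null(filt[[ci]])) {
            filt[[ci]]
          } else if (mode == "rate") {
            drop(nef_decode(net$ensembles[[comp]], ens_in[[comp]],
                            decs[[ci]]))
          } else {
            drop(matrix(outputs[[comp]], 1) %*% decs[[ci]])
          }
        }
        probes_out[[pn]][[k]] <- c(t, val)
      }
    }
  })
  lapply(probes_out, function(rows) {
    m <- do.call(rbind, rows)
    colnames(m) <- c("time", paste0("v", seq_len(ncol(m) - 1)))
    m
  })
}
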