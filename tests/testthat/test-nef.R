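test_that("tuning curves hit zero at the intercept and max rate at radius", {
  for (kind in c("relu", "lif")) {
    e <- nef_ensemble(3, dim = 1, max_rates = c(1, 2, 4),
                      intercepts = c(-0.5, 0, 0.5), neuron_kind = kind,
                      seed = 5L)
    r_pos <- nef_rates(e, 1)[1, ]
    r_neg <- nef_rates(e, -1)[1, ]
    aligned <- ifelse(e$encoders[, 1] > 0, r_pos, r_neg)
    expect_equal(aligned, e$max_rates, tolerance = 0.01)
    for (i in 1:3) {
      x_int <- e$radius * e$intercepts[i] * e$encoders[i, 1]
      expect_equal(nef_rates(e, x_int)[1, i], 0, tolerance = 1e-8)
    }
  }
  # low ephys-scale LIF rates survive in double precision (no silencing)
  e4 <- nef_ensemble(50, dim = 1, max_rates = rep(c(0.5, 1, 2, 4), 13)[1:50],
                     intercepts = seq(-0.9, 0.9, length.out = 50),
                     neuron_kind = "lif", seed = 6L)
  r4 <- nef_rates(e4, 1)[1, ]
  active <- e4$encoders[, 1] > 0
  expect_true(all(r4[active] > 0))
})

test_that("least-squares decoders reach reference accuracy", {
  e <- nef_ensemble(100, dim = 1, neuron_kind = "lif", seed = 1L)
  grid <- matrix(seq(-1, 1, length.out = 1000), ncol = 1)

  # f = 0 decodes to (numerically) zero
  d0 <- compute_decoders(e, function(x) x * 0, seed = 2L)
  expect_lt(max(abs(nef_decode(e, grid, d0))), 1e-6)

  # identity within 5% of the radius, evaluated on a 1000-point grid
  di <- compute_decoders(e, identity, seed = 2L)
  rmse <- sqrt(mean((nef_decode(e, grid, di) - grid)^2))
  expect_lt(rmse, 0.05 * e$radius)

  # doubling the population does not increase the median RMSE (20 seeds)
  rmse_n <- function(n, s) {
    en <- nef_ensemble(n, dim = 1, neuron_kind = "lif", seed = s)
    d <- compute_decoders(en, identity, seed = s + 1L)
    sqrt(mean((nef_decode(en, grid, d) - grid)^2))
  }
  r100 <- vapply(1:20, function(s) rmse_n(100L, s), numeric(1))
  r200 <- vapply(1:20, function(s) rmse_n(200L, s + 100L), numeric(1))
  expect_lte(stats::median(r200), stats::median(r100))
})

test_that("synaptic low-pass filter matches its closed form", {
  expect_equal(lowpass_step(0.3, 0.3, 0.1, 0.001), 0.3)
  # step response: after time tau the state sits at 1 - exp(-1)
  s <- 0
  for (k in 1:100) s <- lowpass_step(s, 1, tau = 0.1, dt = 0.001)
  expect_equal(s, 1 - exp(-1), tolerance = 1e-12)
  # tiny tau tracks the input almost immediately
  expect_equal(lowpass_step(0, 1, tau = 1e-9, dt = 0.001), 1,
               tolerance = 1e-6)
  expect_error(lowpass_step(0, 1, tau = 0, dt = 0.001))
})

test_that("neural integrator integrates, does not drift, and is symmetric", {
  # zero input -> no drift
  p <- 0.4
  for (k in 1:1000) p <- integrator_step(p, 0, 0.1, 0.001)
  expect_equal(p, 0.4)
  # dt << tau2: one step approximates p + v dt
  expect_equal(integrator_step(0, 0.5, 0.1, 0.001), 0.5 * 0.001,
               tolerance = 0.006)
  # integrating v then -v returns to the start
  p <- 0
  for (k in 1:500) p <- integrator_step(p, 0.5, 0.1, 0.001)
  expect_gt(p, 0.2)
  for (k in 1:500) p <- integrator_step(p, -0.5, 0.1, 0.001)
  expect_equal(p, 0, tolerance = 1e-12)
})

test_that("spiking LIF dynamics reproduce rate-mode statistics", {
  # per-neuron 1-second spike counts match the rate-mode prediction
  e <- nef_ensemble(30, dim = 1, neuron_kind = "lif", seed = 4L)
  rates <- nef_rates(e, 0.7)[1, ]
  set.seed(11)
  st <- fishnav:::ens_spike_state(e, 0.7)
  cnt <- numeric(30)
  for (k in 1:1000) {
    s <- fishnav:::ens_spike_step(e, 0.7, st, 1e-3)
    st <- s$state
    cnt <- cnt + s$spikes * 1e-3
  }
  expect_lt(max(abs(cnt - rates)), 1.5)   # within quantization of counts

  # spiking integrator: constant 0.5 for 1 s lands within 5% of 0.5
  e2 <- nef_ensemble(100, dim = 1, neuron_kind = "lif", seed = 2L)
  dec <- compute_decoders(e2, identity, seed = 3L)
  set.seed(12)
  st2 <- fishnav:::ens_spike_state(e2, 0.5)
  p <- 0
  vf <- 0.5
  for (k in 1:1000) {
    s <- fishnav:::ens_spike_step(e2, 0.5, st2, 1e-3)
    st2 <- s$state
    vf <- lowpass_step(vf, drop(matrix(s$spikes, 1) %*% dec), 0.02, 1e-3)
    p <- integrator_step(p, vf, 0.1, 1e-3)
  }
  expect_equal(p, 0.5, tolerance = 0.05)
})

test_that("winner-take-all equals argmax with deterministic tie-breaks", {
  expect_equal(winner_take_all(c(0.2, 0.9, 0.1))$index, 2L)
  expect_equal(winner_take_all(rep(1, 5))$index, 1L)   # tie -> lowest index
  expect_equal(winner_take_all(sort(runif(8)))$index, 8L)
  set.seed(21)
  for (k in 1:100) {
    u <- stats::runif(sample(2:20, 1))
    w <- winner_take_all(u)
    expect_identical(w$index, which.max(u))
    expect_equal(w$action[w$index], 1)
    expect_equal(sum(w$action), 1)
  }
  expect_error(winner_take_all(numeric(0)), "empty")
  # temporal smoothing converges to the argmax of a constant input
  u <- c(0.1, 0.8, 0.3)
  st <- c(1, 0, 0)   # stale state favoring channel 1
  for (k in 1:2000) {
    w <- winner_take_all(u, tau = 0.05, state = st)
    st <- w$state
  }
  expect_equal(w$index, 2L)
})

test_that("network simulation relays, filters, and reproduces under seed", {
  net <- nef_network()
  net <- add_node(net, "in", function(t) sin(2 * pi * t))
  net <- add_ensemble(net, "ens",
                      nef_ensemble(100, 1, neuron_kind = "lif", seed = 5L))
  net <- add_connection(net, "in", "ens", synapse = 0.005)
  net <- add_connection(net, "ens", "readout", synapse = 0.02)
  net <- add_probe(net, "p", "ens")

  expect_equal(nrow(nef_simulate(net, 0, mode = "rate")$p), 0)
  expect_error(nef_simulate(add_probe(net, "bad", "ghost"), 0.1),
               "unconnected probe")

  out <- nef_simulate(net, 1, mode = "rate", seed = 6L)$p
  # reference: the input passed through both synaptic filters
  sig <- 0
  ref <- numeric(1000)
  acc <- 0
  for (k in 1:1000) {
    sig <- lowpass_step(sig, sin(2 * pi * k * 1e-3), 0.005, 1e-3)
    acc <- lowpass_step(acc, sig, 0.02, 1e-3)
    ref[k] <- acc
  }
  expect_lt(sqrt(mean((out[, 2] - ref)^2)), 0.02)

  s1 <- nef_simulate(net, 0.2, mode = "spiking", seed = 9L)$p
  s2 <- nef_simulate(net, 0.2, mode = "spiking", seed = 9L)$p
  expect_identical(s1, s2)
})
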