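# A connectionless miniature network: 14 E "clusters" of one neuron,
# one-neuron I clusters, no synapses. Lets single-neuron dynamics be
# checked against closed forms.
lone_params <- function(...) {
  network_params(e_cluster_size = 1, i_cluster_size = 1, background_e = 0,
                 p_ee = 0, p_ei = 0, p_ie = 0, p_ii = 0, ...)
}

test_that("stimulus waveform vanishes at onset and peaks at the gain", {
  sp <- stimulus_spec(gain = 60, tau_d = 0.160, tau_r = 0.020)
  expect_equal(stimulus_waveform(sp$onset, sp), 0)
  expect_equal(stimulus_waveform(sp$onset - 1, sp), 0)
  # numerical maximization vs closed-form peak location
  tt <- seq(0, 1.5, by = 1e-5)
  f <- stimulus_waveform(tt, sp)
  t_star <- sp$tau_d * sp$tau_r * log(sp$tau_d / sp$tau_r) /
    (sp$tau_d - sp$tau_r)
  expect_equal(max(f), 60, tolerance = 1e-6)
  expect_equal(tt[which.max(f)], t_star, tolerance = 1e-4)
  # head + tail = full pointwise
  head_f <- stimulus_waveform(tt, stimulus_spec(60, segment = "head"))
  tail_f <- stimulus_waveform(tt, stimulus_spec(60, segment = "tail"))
  expect_equal(head_f + tail_f, f)
  expect_true(all(head_f[tt > 0.5] == 0))
  expect_true(all(tail_f[tt <= 0.5] == 0))
  expect_error(stimulus_spec(60, tau_d = 0.02, tau_r = 0.02), "tau_d")
})

test_that("gate ramps linearly from 0 to 1 over half a second", {
  g <- gate_spec(1.3)
  expect_equal(gate_signal(1.3, g), 0)
  expect_equal(gate_signal(1.3 + 0.25, g), 0.5)
  expect_equal(gate_signal(1.3 + 0.5, g), 1)
  expect_equal(gate_signal(0, g), 0)
  expect_equal(gate_signal(3, g), 1)
  tt <- seq(0, 3, by = 0.01)
  gg <- gate_signal(tt, g)
  expect_true(all(diff(gg) >= 0) && all(gg >= 0 & gg <= 1))
})

test_that("silencing pulse is a square wave with the right integral", {
  p <- silence_pulse(center = 0.25, duration = 0.5, strength = 100)
  expect_equal(silencing_pulse(0.25, p), 100)
  expect_equal(silencing_pulse(-0.1, p), 0)
  expect_equal(silencing_pulse(0.75, p), 0)
  # quadrature of the pulse equals strength x duration
  tt <- seq(0, 3, by = 1e-4)
  expect_equal(sum(silencing_pulse(tt, p)) * 1e-4, 100 * 0.5,
               tolerance = 1e-2)
  expect_equal(length(silencing_pulse(1:5, NULL)), 5)
})

test_that("an isolated neuron matches the LIF firing-rate closed form", {
  net <- build_network(lone_params(), seed = 1)
  cc <- neuron_params(i_ext_e = 1.5, i_ext_i = 0.5, noise_sd = 0)
  sp <- simulate_trial(net, cc, stimulus = NULL, taste = NULL,
                       duration = 4, seed = 1,
                       v0 = rep(0, net$n_e + net$n_i))
  # E: tau_m 20, V_th 20, V_r 0, tau_r 5 -> r in Hz
  r_closed <- 1000 / (cc$tau_r_e + cc$tau_m_e *
                        log((1.5 * cc$tau_m_e) /
                              (1.5 * cc$tau_m_e - cc$v_th)))
  e_rate <- sum(sp$neuron <= net$n_e) / net$n_e / 4
  expect_lt(abs(e_rate - r_closed), 1.5)
  # I neurons at tau_m 10 with drive 0.5 (5 mV asymptote) stay silent
  expect_identical(sum(sp$neuron > net$n_e), 0L)
})

test_that("subthreshold drive without synapses yields no spikes", {
  net <- build_network(lone_params(), seed = 2)
  cc <- neuron_params(i_ext_e = 0.9, i_ext_i = 0.9, noise_sd = 0)
  sp <- simulate_trial(net, cc, stimulus = NULL, taste = NULL,
                       duration = 2, seed = 1,
                       v0 = rep(0, net$n_e + net$n_i))
  expect_length(sp$time, 0)
})

test_that("simulation is bitwise deterministic under a seed", {
  p <- network_params(e_cluster_size = 20, i_cluster_size = 6,
                      background_e = 40)
  net <- build_network(p, seed = 3)
  cc <- neuron_params()
  a <- simulate_trial(net, cc, duration = 0.5, seed = 9)
  b <- simulate_trial(net, cc, duration = 0.5, seed = 9)
  expect_identical(a$time, b$time)
  expect_identical(a$neuron, b$neuron)
  c <- simulate_trial(net, cc, duration = 0.5, seed = 10)
  expect_false(identical(a$time, c$time))
})

test_that("no neuron violates its refractory period", {
  p <- network_params(e_cluster_size = 20, i_cluster_size = 6,
                      background_e = 40, j_ee = 1.2, j_ie = 1.0)
  net <- build_network(p, seed = 4)
  cc <- neuron_params(i_ext_e = 1.6, i_ext_i = 1.2)
  sp <- simulate_trial(net, cc, duration = 1, seed = 5)
  for (j in unique(sp$neuron)) {
    isi <- diff(sp$time[sp$neuron == j])
    tau_r <- if (j <= net$n_e) cc$tau_r_e else cc$tau_r_i
    if (length(isi)) expect_gte(min(isi) * 1000, tau_r - 1e-9)
  }
})

test_that("halving the Euler step barely changes a deterministic run", {
  net <- build_network(lone_params(), seed = 6)
  cc <- neuron_params(i_ext_e = 1.3, i_ext_i = 0.5, noise_sd = 0)
  v0 <- rep(0, net$n_e + net$n_i)
  n1 <- length(simulate_trial(net, cc, stimulus = NULL, taste = NULL,
                              duration = 1, dt = 0.05, v0 = v0)$time)
  n2 <- length(simulate_trial(net, cc, stimulus = NULL, taste = NULL,
                              duration = 1, dt = 0.025, v0 = v0)$time)
  expect_lte(abs(n1 - n2) / net$n_e, 1)
})

test_that("the unstimulated network expresses metastable cluster epochs", {
  net <- build_network(network_params(), seed = 1)
  cc <- neuron_params()
  sp <- simulate_trial(net, cc, stimulus = NULL, taste = NULL,
                       duration = 6, seed = 3)
  e_rate <- sum(sp$neuron <= net$n_e) / net$n_e / 6
  expect_gt(e_rate, 1); expect_lt(e_rate, 15)
  r <- cluster_rate_series(sp, net, bin = 0.05)
  hi <- r > 2 * mean(r)
  # several clusters take turns in high-rate epochs with finite dwells
  expect_gte(sum(rowSums(hi) > 0), 2)
  dwell <- unlist(apply(hi, 1, function(x) {
    rl <- rle(x); rl$lengths[rl$values] }))
  expect_gt(length(dwell), 1)
  expect_gt(mean(dwell) * 50, 100)      # dwells of order 10^2-10^3 ms
  expect_true(any(!hi[, ncol(hi)]) || any(!hi[, 1]))
})
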