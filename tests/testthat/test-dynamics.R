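test_that("background drive relaxes to its fixed point and decays linearly", {
  p <- model_params()
  # noise off: fixed point R_m * I_0 = 1.5 mV
  v <- 0
  for (k in 1:2000) v <- ou_step_background(v, p, noise = 0)
  expect_equal(v, p$R_m * p$I_0, tolerance = 1e-8)
  expect_equal(p$R_m * p$I_0, 1.5)
  # no current: exponential decay with tau_syn
  p0 <- model_params(I_0 = 0)
  v <- 3
  n <- 50
  for (k in seq_len(n)) v <- ou_step_background(v, p0, noise = 0)
  expect_equal(v, 3 * (1 - p0$dt / p0$tau_syn)^n, tolerance = 1e-12)
  expect_equal(v, 3 * exp(-n * p0$dt / p0$tau_syn), tolerance = 0.05)
})

test_that("background drive reproduces the stationary moments", {
  # Monte-Carlo vs closed form: mean R_m I_0 = 1.5 mV,
  # sd R_m sigma_wn / sqrt(2 tau_syn) = 5 mV
  p <- model_params()
  set.seed(42)
  n_traj <- 4000
  v <- rep(0, n_traj)
  for (k in 1:1000) v <- ou_step_background(v, p, noise = rnorm(n_traj))
  se_mean <- 5 / sqrt(n_traj)
  se_sd <- 5 / sqrt(2 * (n_traj - 1))
  expect_lt(abs(mean(v) - 1.5), 3 * se_mean)
  expect_lt(abs(sd(v) - 5), 3 * se_sd)
})

test_that("stimulus drive has the stated fixed point and decay", {
  p <- model_params()
  # noise off, N_stim = 4, f = 100 Hz: mean 4 * 100 * 1s * h_0
  v <- 0
  for (k in 1:2000) v <- ou_step_stimulus(v, 100, p, noise = 0)
  expect_equal(v, 1680.3, tolerance = 1e-6)
  # f = 0: pure decay, no noise amplitude
  v <- 10
  for (k in 1:25) v <- ou_step_stimulus(v, 0, p, noise = rnorm(1))
  expect_equal(v, 10 * (1 - p$dt / p$tau_syn)^25, tolerance = 1e-12)
  expect_error(ou_step_stimulus(0, -5, p), "non-negative")
  # stationary sd of the Euler chain matches the OU closed form
  set.seed(7)
  n_traj <- 4000
  v <- rep(0, n_traj)
  for (k in 1:1000) v <- ou_step_stimulus(v, 100, p, noise = rnorm(n_traj))
  sd_theory <- sqrt(4 * 100) * p$h_0 / sqrt(2 * p$tau_syn)
  expect_lt(abs(sd(v) - sd_theory), 3 * sd_theory / sqrt(2 * (n_traj - 1)))
})

test_that("PSP traces jump by the arriving weight and decay exponentially", {
  p <- model_params()
  tr <- deliver_spike(0, 3)
  expect_equal(psp_decay(tr, p$tau_syn, p), 3 / exp(1))
  expect_equal(deliver_spike(1, c(2, 4)), 7)  # simultaneous arrivals add
})

test_that("simulated PSP trace equals the explicit delayed-exponential sum", {
  # two neurons, plasticity frozen: the trace of the target neuron must
  # match the sum over the source neuron's spikes to within 1e-9 mV
  p <- frozen_plasticity(model_params(N_e = 2, N_i = 0, assembly_size = 1,
                                      p_c = 1, I_0 = 0, sigma_wn = 0))
  topo <- build_network(p, seed = 1)
  arr <- stcnet:::.network_arrays(topo)
  st <- stcnet:::.initial_state(p, arr$n_syn)
  set.seed(1)
  res <- stcnet:::sim_spiking_cpp(
    arr, unclass(p), st, 0, 2,
    stim_on = 0.1, stim_off = 1.9, stim_f = 100,
    stim_targets = list(0L), nm_breaks = 0, nm_levels = 0,
    snapshot_times = numeric(0), record_neurons = 0:1)
  spikes1 <- res$spike_time[res$spike_neuron == 1]
  expect_gt(length(spikes1), 20)
  check_steps <- seq(1000, 10000, by = 370)
  for (k in check_steps) {
    t_k <- (k - 1) * p$dt  # row k of the trace holds the value at (k-1) dt
    expect_equal(res$trace_psp[k, 2],
                 psp_sum_oracle(t_k, spikes1, rep(p$h_0, length(spikes1)), p),
                 tolerance = 1e-10)
  }
})

test_that("membrane dynamics: relaxation, closed-form ISI, refractoriness", {
  p <- model_params()
  # subthreshold: relaxes toward V_rev, no spike
  st <- list(V = p$V_th - 0.5, refrac_steps = 0L)
  for (k in 1:5000) {
    st <- membrane_step(st$V, st$refrac_steps, params = p)
    expect_false(st$spiked)
  }
  expect_equal(st$V, p$V_rev, tolerance = 1e-6)
  # constant suprathreshold drive: ISI = t_ref + tau_m log((Veq-Vreset)/(Veq-Vth))
  drive <- 20
  isi_pred <- p$t_ref + p$tau_m *
    log((p$V_rev + drive - p$V_reset) / (p$V_rev + drive - p$V_th))
  st <- list(V = p$V_rev, refrac_steps = 0L)
  spikes <- c()
  for (k in 1:3000) {
    st <- membrane_step(st$V, st$refrac_steps, psp = drive, params = p)
    if (st$spiked) spikes <- c(spikes, k * p$dt)
  }
  isi <- diff(spikes)
  expect_true(all(abs(isi - isi_pred) <= 2 * p$dt + 1e-12))
  # after a spike the potential is pinned at -70 mV for exactly 2 ms
  st <- membrane_step(p$V_th + 1, 0L, params = p)
  expect_true(st$spiked)
  expect_equal(st$refrac_steps, 10L)
  for (k in 1:10) {
    st <- membrane_step(st$V, st$refrac_steps, psp = drive, params = p)
    expect_equal(st$V, -70)
    expect_false(st$spiked)
  }
  st <- membrane_step(st$V, st$refrac_steps, psp = drive, params = p)
  expect_gt(st$V, -70)  # integrating again
})

test_that("network is silent and at rest without noise or stimulation", {
  p <- frozen_plasticity(tiny_params(I_0 = 0, sigma_wn = 0))
  topo <- build_network(p, seed = 2)
  arr <- stcnet:::.network_arrays(topo)
  st <- stcnet:::.initial_state(p, arr$n_syn)
  st$V <- st$V + 5  # start displaced
  set.seed(1)
  res <- stcnet:::sim_spiking_cpp(
    arr, unclass(p), st, 0, 0.5, numeric(0), numeric(0), numeric(0),
    list(), 0, 0, numeric(0), integer(0))
  expect_equal(length(res$spike_time), 0)
  expect_equal(res$state$V, rep(p$V_rev, 75), tolerance = 1e-3)
})

test_that("per-neuron inter-spike intervals respect the refractory period", {
  p <- scaled_params()
  topo <- build_network(p, seed = 1)
  run <- run_experiment(p, topo, recall = "10s", seed = 1,
                        timeline = protocol_timeline("10s", learning_f = 60,
                                                     settle = 1))
  isi <- unlist(tapply(run$raster$time, run$raster$neuron, diff))
  expect_gt(length(isi), 100)
  expect_true(all(isi >= p$t_ref - 1e-12))
})

test_that("binning yields the stated shape and half-open conventions", {
  r <- spike_raster(c(1, 1, 2, 3), c(0.0005, 0.0504, 0.003, 0.1),
                    n_neurons = 3,
                    windows = data.frame(t0 = 0, t1 = 0.2))
  m <- bin_raster(r, 0.001, c(0, 0.1))
  expect_equal(dim(m), c(3, 100))   # 100 ms at 1 ms bins -> 100 columns
  expect_equal(sum(m), 3)           # spike at 0.1 is outside [0, 0.1)
  expect_equal(which(m[1, ] == 1), c(1, 51))
  expect_equal(which(m[2, ] == 1), 4)
  expect_true(all(bin_raster(r, 0.001, c(0.11, 0.15)) == 0))
  expect_error(bin_raster(r, 0.001, c(0.1, 0.1)), "empty")
  expect_error(bin_raster(r, 0.001, c(0, 0.0105)), "multiple")
  # sliding rate: trailing half-open window (t - w, t]
  r2 <- spike_raster(c(1, 1, 1, 1, 1), c(0.5, 0.6, 0.7, 0.8, 1.0),
                     n_neurons = 2, windows = data.frame(t0 = 0, t1 = 1))
  expect_equal(sliding_rate(r2, 1.0)[1], 8)   # 4 spikes in (0.5, 1]: 0.5 excluded
  expect_equal(sliding_rate(r2, 1.0)[2], 0)
  expect_error(sliding_rate(r2, 1.2), "cover")
})
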