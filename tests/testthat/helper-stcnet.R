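# Shared fixtures and reference integrators for the test suite.

# a network small enough for full-protocol runs inside unit tests
tiny_params <- function(...) {
  model_params(N_e = 60L, N_i = 15L, assembly_size = 10L, ...)
}

# parameters that freeze the E->E plasticity (calcium thresholds far
# out of reach, no plasticity noise): weights stay exactly at h_0
frozen_plasticity <- function(p) {
  p$theta_d <- 1e6
  p$theta_p <- 2e6
  p$sigma_pl <- 0
  p
}

# reference fine-step integrator of the deterministic weight dynamics
# (early-phase relaxation, protein pool, late phase) over a
# stimulation-free gap; vectorised over synapses, plain forward Euler.
# Requires one synapse per postsynaptic neuron (so the per-neuron sum
# of early-phase changes is just |h - h_0| of that synapse).
fine_consolidation <- function(h, z, p, post_ids, n_e, t_start, t_end, nm,
                               params, dt = params$dt) {
  stopifnot(!anyDuplicated(post_ids))
  n_steps <- round((t_end - t_start) / dt)
  decay <- exp(-0.1 * dt / params$tau_h)
  theta_t <- protein_threshold(nm_at(nm, t_start + (seq_len(n_steps) - 1) * dt))
  p_syn <- p[post_ids]
  for (k in seq_len(n_steps)) {
    p_syn <- p_syn + dt / params$tau_p *
      (params$alpha_p * (abs(h - params$h_0) > theta_t[k]) - p_syn)
    z <- late_phase_step(z, h, p_syn, params, dt = dt)
    h <- params$h_0 + (h - params$h_0) * decay
  }
  p_out <- numeric(n_e)
  p_out[post_ids] <- p_syn
  list(h = h, z = z, p = p_out)
}

# explicit evaluation of the delayed-exponential PSP sum at time t for
# one neuron, given presynaptic spike times and (signed) weights
psp_sum_oracle <- function(t, spike_times, weights, params) {
  dt_arr <- t - spike_times - params$t_ax_delay
  sum(weights * exp(-pmax(dt_arr, 0) / params$tau_syn) * (dt_arr >= -1e-12))
}

expect_same_run <- function(a, b) {
  expect_equal(a$raster$time, b$raster$time)
  expect_equal(a$raster$neuron, b$raster$neuron)
  expect_equal(a$snapshots$post_recall$h, b$snapshots$post_recall$h)
  expect_equal(a$snapshots$post_recall$z, b$snapshots$post_recall$z)
  expect_equal(a$state_final$p, b$state_final$p)
}
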