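#' Ornstein-Uhlenbeck step for the background drive
#'
#' One Euler-Maruyama step of the background contribution to the
#' membrane potential, `tau_syn * dV_bg/dt = -V_bg + R_m * (I_0 +
#' sigma_wn * Gamma)`, where `Gamma` is Gaussian white noise with
#' variance `1/dt`.  The stationary mean is `R_m * I_0` and the
#' stationary standard deviation `R_m * sigma_wn / sqrt(2 * tau_syn)`.
#'
#' @param v_bg current background potential, mV (vectorised).
#' @param params an `stc_params` object.
#' @param noise standard-normal draw(s); defaults to `rnorm`.
#' @param dt step size, s (defaults to `params$dt`).
#' @return updated background potential, mV.
#' @export
ou_step_background <- function(v_bg, params, noise = rnorm(length(v_bg)),
                               dt = params$dt) {
  a <- dt / params$tau_syn
  v_bg + a * (params$R_m * params$I_0 - v_bg) +
    params$R_m * params$sigma_wn * sqrt(dt) / params$tau_syn * noise
}

#' Ornstein-Uhlenbeck step for the stimulus drive
#'
#' One Euler-Maruyama step of the stimulus contribution
#' `tau_syn * dV_stim/dt = -V_stim + (N_stim * f_stim +
#' sqrt(N_stim * f_stim) * Gamma) * 1s * h_0`, modelling `N_stim`
#' putative input neurons firing at `f_stim` through synapses of weight
#' `h_0`.  The process is computed independently for each stimulated
#' neuron; outside stimulation epochs `f_stim = 0` and the trace
#' decays.
#'
#' @param v_stim current stimulus potential, mV (vectorised).
#' @param f_stim stimulation frequency, Hz (scalar, >= 0).
#' @inheritParams ou_step_background
#' @return updated stimulus potential, mV.
#' @export
ou_step_stimulus <- function(v_stim, f_stim, params,
                             noise = rnorm(length(v_stim)),
                             dt = params$dt) {
  if (f_stim < 0) stop("stimulation frequency must be non-negative")
  a <- dt / params$tau_syn
  mu <- params$N_stim * f_stim * params$h_0          # * 1 s, in mV
  sdv <- sqrt(params$N_stim * f_stim) * params$h_0 * sqrt(dt) / params$tau_syn
  v_stim + a * (mu - v_stim) + sdv * noise
}

#' Postsynaptic-potential trace updates
#'
#' The summed PSP drive of a neuron is kept as a single exponential
#' trace: between spike arrivals it decays with `tau_syn`
#' (`psp_decay`), and each arriving spike adds its (signed) synaptic
#' weight instantaneously (`deliver_spike`).  The trace is
#' mathematically identical to the explicit double sum over presynaptic
#' spike times with axonal delay.
#'
#' @param trace current trace value, mV.
#' @param elapsed time since the trace was last valid, s.
#' @param params an `stc_params` object.
#' @return updated trace, mV.
#' @export
psp_decay <- function(trace, elapsed, params) {
  trace * exp(-elapsed / params$tau_syn)
}

#' @rdname psp_decay
#' @param weights signed weights (mV) of the spikes arriving now;
#'   inhibitory weights enter negatively.
#' @export
deliver_spike <- function(trace, weights) {
  trace + sum(weights)
}

#' Single-neuron membrane step
#'
#' One forward-Euler step of the leaky integrate-and-fire membrane
#' equation `tau_m * dV/dt = V_rev - V + V_psp + V_bg + V_stim`.
#' During the refractory period the potential is pinned at `V_reset`.
#' When the updated potential reaches `V_th` a spike is emitted, the
#' potential is reset and the refractory counter set to `t_ref / dt`
#' steps.
#'
#' @param V membrane potential, mV.
#' @param refrac_steps remaining refractory steps (integer >= 0).
#' @param psp,v_bg,v_stim drive components, mV.
#' @param params an `stc_params` object.
#' @return list with elements `V`, `refrac_steps`, `spiked`.
#' @export
membrane_step <- function(V, refrac_steps, psp = 0, v_bg = 0, v_stim = 0,
                          params = model_params()) {
  if (!is.finite(V)) stop("membrane potential is non-finite")
  if (refrac_steps > 0) {
    return(list(V = params$V_reset, refrac_steps = refrac_steps - 1L,
                spiked = FALSE))
  }
  v <- V + params$dt / params$tau_m *
    (params$V_rev - V + psp + v_bg + v_stim)
  if (v >= params$V_th) {
    list(V = params$V_reset,
         refrac_steps = as.integer(round(params$t_ref / params$dt)),
         spiked = TRUE)
  } else {
    list(V = v, refrac_steps = 0L, spiked = FALSE)
  }
}

#' Spike raster container
#'
#' A data.frame of spike events (`neuron`, 1-based; `time`, s) with
#' attributes recording the population size and the covered time
#' window(s).
#'
#' @param neuron integer vector of neuron ids (1-based).
#' @param time numeric vector of spike times, s.
#' @param n_neurons total number of neurons.
#' @param windows a data.frame with columns `t0`, `t1` listing the
#'   simulated (covered) intervals; a raster may cover disjoint spans,
#'   e.g. the learning phase and a late recall phase.
#' @return an object of classes `stc_raster` and `data.frame`.
#' @export
spike_raster <- function(neuron, time, n_neurons,
                         windows = data.frame(t0 = min(time, Inf),
                                              t1 = max(time, -Inf))) {
  stopifnot(length(neuron) == length(time))
  o <- order(time, neuron)
  r <- data.frame(neuron = as.integer(neuron)[o], time = as.numeric(time)[o])
  attr(r, "n_neurons") <- as.integer(n_neurons)
  attr(r, "windows") <- windows
  class(r) <- c("stc_raster", "data.frame")
  r
}

#' @export
print.stc_raster <- function(x, ...) {
  w <- attr(x, "windows")
  cat("stc_raster:", nrow(x), "spikes from", attr(x, "n_neurons"),
      "neurons over",
      paste(sprintf("[%.4g, %.4g]", w$t0, w$t1), collapse = ", "), "s\n")
  invisible(x)
}

# TRUE if [t0, t1] is inside one covered window of the raster
raster_covers <- function(raster, t0, t1) {
  w <- attr(raster, "windows")
  if (is.null(w)) return(TRUE)
  any(w$t0 <= t0 + 1e-9 & w$t1 >= t1 - 1e-9)
}

#' Bin a spike raster into a boolean matrix
#'
#' Counts spikes into bins of `bin_width` over `[window[1],
#' window[2])`; an entry is 1 if the neuron spiked at least once in the
#' bin.  At 1 ms bins the refractory period guarantees at most one
#' spike per bin.
#'
#' @param raster an `stc_raster` (or data.frame with `neuron`, `time`).
#' @param bin_width bin width, s (e.g. 0.001).
#' @param window numeric length-2: start (inclusive) and end
#'   (exclusive) of the binned span, s; its length must be a multiple
#'   of `bin_width`.
#' @return integer matrix of shape (neurons, bins).
#' @examples
#' r <- spike_raster(c(1, 1, 2), c(0.0005, 0.050, 0.003), n_neurons = 3)
#' bin_raster(r, 0.001, c(0, 0.1))  # 3 x 100, three ones
#' @export
bin_raster <- function(raster, bin_width, window) {
  stopifnot(length(window) == 2L)
  len <- window[2] - window[1]
  if (len <= 0) stop("empty binning window")
  n_bins <- round(len / bin_width)
  if (abs(n_bins * bin_width - len) > 1e-9) {
    stop("window length must be a multiple of the bin width")
  }
  n_neurons <- attr(raster, "n_neurons")
  if (is.null(n_neurons)) n_neurons <- max(raster$neuron)
  m <- matrix(0L, n_neurons, n_bins)
  sel <- raster$time >= window[1] - 1e-12 & raster$time < window[2] - 1e-12
  if (any(sel)) {
    b <- pmin(floor((raster$time[sel] - window[1]) / bin_width) + 1, n_bins)
    m[cbind(raster$neuron[sel], b)] <- 1L
  }
  m
}
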