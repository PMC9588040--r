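#' Neuromodulator-dependent protein synthesis threshold
#'
#' The threshold that the summed early-phase weight change of a neuron
#' must exceed to trigger synthesis of plasticity-related proteins:
#' `theta_pro(NM) = 1 / (NM + 0.001)` (mV).  Higher neuromodulator
#' concentrations lower the threshold; with no neuromodulator present
#' the threshold (1000 mV) is unreachable in the reference network.
#'
#' @param nm neuromodulator concentration (dimensionless, >= 0;
#'   vectorised).
#' @return threshold in mV.
#' @examples
#' protein_threshold(c(0, 0.06, 0.18))  # 1000, 16.39, 5.52
#' @export
protein_threshold <- function(nm) {
  if (any(nm < 0)) stop("neuromodulator concentration must be non-negative")
  1 / (nm + 0.001)
}

#' Calcium update at a plastic synapse
#'
#' Advances the postsynaptic calcium concentration by `dt`: exponential
#' decay with `tau_c`, plus `c_pre` for every presynaptic spike whose
#' delayed (by `t_c_delay`) signal arrives in this step, plus `c_post`
#' for every postsynaptic spike in this step.
#'
#' @param c calcium concentration (vectorised).
#' @param params an `stc_params` object.
#' @param n_pre,n_post number of (delayed) presynaptic arrivals and
#'   postsynaptic spikes in this step.
#' @param dt step size, s.
#' @return updated calcium concentration.
#' @export
calcium_step <- function(c, params, n_pre = 0, n_post = 0, dt = params$dt) {
  c * exp(-dt / params$tau_c) + n_pre * params$c_pre + n_post * params$c_post
}

#' Early-phase weight update
#'
#' One Euler-Maruyama step of the calcium-based early-phase dynamics:
#' relaxation toward `h_0` (rate `0.1/tau_h`), potentiation toward
#' 10 mV at rate `gamma_p` while calcium exceeds `theta_p`, depression
#' at rate `gamma_d` while calcium exceeds `theta_d`, plus a noise term
#' that is active only while calcium is above either threshold.  The
#' result is clipped to [0, 10] mV.
#'
#' @param h early-phase weight, mV (vectorised).
#' @param c calcium concentration (vectorised).
#' @param params an `stc_params` object.
#' @param noise standard-normal draw(s).
#' @param dt step size, s.
#' @return updated early-phase weight, mV.
#' @export
early_phase_step <- function(h, c, params, noise = 0, dt = params$dt) {
  ip <- c > params$theta_p
  id <- c > params$theta_d
  drift <- 0.1 * (params$h_0 - h) + params$gamma_p * (10 - h) * ip -
    params$gamma_d * h * id
  h2 <- h + dt / params$tau_h * drift +
    params$sigma_pl * sqrt((ip + id) * dt / params$tau_h) * noise
  pmin(pmax(h2, 0), 10)
}

#' Synaptic tag indicator
#'
#' A synapse is tagged when its early-phase deviation from baseline
#' exceeds the tagging threshold: `|h - h_0| > theta_tag`.  The sign of
#' the deviation distinguishes an LTP tag (`h > h_0`) from an LTD tag.
#'
#' @param h early-phase weight, mV (vectorised).
#' @param params an `stc_params` object.
#' @param sign if `TRUE`, return +1 / -1 / 0 for LTP tag, LTD tag, or
#'   untagged instead of a logical.
#' @return logical (or signed integer) tag indicator.
#' @export
tag_indicator <- function(h, params, sign = FALSE) {
  dev <- h - params$h_0
  tagged <- abs(dev) > params$theta_tag
  if (!sign) return(tagged)
  as.integer(tagged) * ifelse(dev > 0, 1L, -1L)
}

#' Protein pool update
#'
#' One Euler step of the plasticity-related protein dynamics
#' `tau_p * dp/dt = -p + alpha * Theta[sum_j |h_j - h_0| - theta_pro(NM)]`,
#' where the sum runs over the incoming plastic synapses of the neuron
#' and the synthesis threshold depends on the neuromodulator
#' concentration via [protein_threshold()].
#'
#' @param p protein amount (vectorised per neuron).
#' @param early_change_sum per-neuron sum of `|h - h_0|` over incoming
#'   E-to-E synapses, mV.
#' @param nm neuromodulator concentration.
#' @param params an `stc_params` object.
#' @param dt step size, s.
#' @return updated protein amount.
#' @export
protein_step <- function(p, early_change_sum, nm, params, dt = params$dt) {
  target <- params$alpha_p * (early_change_sum > protein_threshold(nm))
  p + dt / params$tau_p * (target - p)
}

#' Late-phase weight update
#'
#' One Euler step of the late-phase dynamics: while the synapse carries
#' an LTP tag and proteins are available, `z` grows toward 1 at rate
#' `p/tau_z`; while it carries an LTD tag, `z` decays toward -0.5.
#' Without a tag, or with `p = 0`, the late phase is frozen.  `z` is
#' clipped to [-0.5, 1].
#'
#' @param z late-phase weight (dimensionless, vectorised).
#' @param h early-phase weight, mV (determines the tag).
#' @param p protein amount of the postsynaptic neuron.
#' @param params an `stc_params` object.
#' @param dt step size, s.
#' @return updated late-phase weight.
#' @export
late_phase_step <- function(z, h, p, params, dt = params$dt) {
  ltp <- (h - params$h_0) > params$theta_tag
  ltd <- (params$h_0 - h) > params$theta_tag
  z2 <- z + dt / params$tau_z * (p * (1 - z) * ltp - p * (z + 0.5) * ltd)
  pmin(pmax(z2, -0.5), 1)
}

#' Total synaptic weight of a plastic synapse
#'
#' `w = h + h_0 * z`, the sum of the early-phase weight and the
#' late-phase weight normalised by the baseline.  Also returned as a
#' percentage of baseline (100% = unpotentiated), the scale used for
#' potentiation contours.
#'
#' @param h early-phase weight, mV.
#' @param z late-phase weight (dimensionless).
#' @param params an `stc_params` object.
#' @return list with numeric vectors `w` (mV) and `percent`.
#' @examples
#' total_weight(4.20075, 0.5, model_params())$percent  # 150
#' @export
total_weight <- function(h, z, params) {
  w <- h + params$h_0 * z
  list(w = w, percent = 100 * w / params$h_0)
}

#' Neuromodulator schedule
#'
#' A piecewise-constant neuromodulator concentration over time.  The
#' onset is measured from the end of the learning stimulation; a
#' duration of `Inf` (or `"max"`) keeps the level on for the rest of
#' the simulation.  `nm_constant()` holds the level for the entire
#' simulation including the learning phase.
#'
#' @param level neuromodulator concentration (>= 0).
#' @param onset_min onset in minutes after the end of learning.
#' @param duration_min duration in minutes, or `Inf` / `"max"`.
#' @param t_learn_end end of the learning stimulation, s.
#' @return an object of class `stc_nm` with fields `breaks` (s) and
#'   `levels`; `nm_at()` evaluates it at arbitrary times.
#' @export
nm_schedule <- function(level, onset_min = 0, duration_min = Inf,
                        t_learn_end = 11.1) {
  if (identical(duration_min, "max")) duration_min <- Inf
  stopifnot(level >= 0, onset_min >= 0, duration_min > 0)
  t_on <- t_learn_end + 60 * onset_min
  if (is.finite(duration_min)) {
    breaks <- c(0, t_on, t_on + 60 * duration_min)
    levels <- c(0, level, 0)
  } else {
    breaks <- c(0, t_on)
    levels <- c(0, level)
  }
  structure(list(breaks = breaks, levels = levels, level = level,
                 onset_min = onset_min, duration_min = duration_min),
            class = "stc_nm")
}

#' @rdname nm_schedule
#' @export
nm_constant <- function(level) {
  stopifnot(level >= 0)
  structure(list(breaks = 0, levels = level, level = level,
                 onset_min = 0, duration_min = Inf),
            class = "stc_nm")
}

#' @rdname nm_schedule
#' @param schedule an `stc_nm` object.
#' @param t time(s), s.
#' @export
nm_at <- function(schedule, t) {
  idx <- findInterval(t, schedule$breaks)
  idx[idx < 1L] <- 1L
  schedule$levels[idx]
}

#' @export
print.stc_nm <- function(x, ...) {
  if (length(x$levels) == 1L) {
    cat("stc_nm: constant level", x$level, "\n")
  } else {
    cat("stc_nm: level", x$level, "from", x$breaks[2], "s",
        if (length(x$breaks) > 2) paste("to", x$breaks[3], "s") else "onward",
        "\n")
  }
  invisible(x)
}

#' Fast-forward the weight dynamics across a stimulation-free gap
#'
#' During the consolidation phase between learning and a late recall
#' no stimulation is applied and spiking is sparse, so the calcium
#' concentration stays below the plasticity thresholds.  The
#' early-phase deviations then decay exponentially at rate `0.1/tau_h`
#' (computed analytically), while the tag indicators, the per-neuron
#' sums of early-phase change, the protein pools and the late-phase
#' weights are integrated on a coarse grid of `dt_ff`.  The stochastic
#' term of the early-phase equation is inactive below the calcium
#' thresholds and therefore absent here.
#'
#' @param h,z early-/late-phase weights per synapse.
#' @param p protein amount per excitatory neuron (length `n_e`).
#' @param post_ids postsynaptic neuron per synapse (1-based, <= n_e).
#' @param n_e number of excitatory neurons.
#' @param t_start,t_end gap boundaries, s (`t_end >= t_start`).
#' @param nm an `stc_nm` schedule.
#' @param params an `stc_params` object.
#' @param dt_ff coarse integration step, s (default 0.1).
#' @return list with updated `h`, `z`, `p`.
#' @export
fast_forward <- function(h, z, p, post_ids, n_e, t_start, t_end, nm, params,
                         dt_ff = 0.1) {
  if (t_end < t_start) stop("fast-forward end time precedes start time")
  stopifnot(length(h) == length(z), length(h) == length(post_ids),
            length(p) == n_e, inherits(nm, "stc_nm"))
  fast_forward_cpp(as.numeric(h), as.numeric(z), as.numeric(p),
                   as.integer(post_ids) - 1L, as.integer(n_e),
                   t_start, t_end,
                   as.numeric(nm$breaks), as.numeric(nm$levels),
                   dt_ff, unclass(params))
}

#' Lifetime of a synaptic tag under pure decay
#'
#' With no further stimulation the early-phase deviation decays as
#' `exp(-0.1 t / tau_h)`; the tag vanishes when it reaches the tagging
#' threshold.  For a synapse potentiated to `2 h_0` this is about
#' 3.1 hours, the time by which consolidation stops.
#'
#' @param h early-phase weight at the start of the decay, mV.
#' @param params an `stc_params` object.
#' @return time until the tag vanishes, s (0 if untagged).
#' @export
tag_lifetime <- function(h, params) {
  dev <- abs(h - params$h_0)
  ifelse(dev <= params$theta_tag, 0,
         params$tau_h / 0.1 * log(dev / params$theta_tag))
}
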