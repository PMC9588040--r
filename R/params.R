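#' Model parameters
#'
#' Constructs the complete set of model constants for the network,
#' neuron, and synapse dynamics.  Units are seconds, millivolts,
#' nanoamperes and megaohms throughout (so that `R_m * I_0` is in mV).
#' Defaults are the reference parameterisation of the model; any field
#' can be overridden by name.
#'
#' The coupling strengths `w_ei` (E to I), `w_ie` (I to E) and `w_ii`
#' (I to I) default to `2*h_0`, `4*h_0` and `4*h_0` respectively and
#' track an overridden `h_0` unless given explicitly.
#'
#' @param ... named parameter overrides, see Details.
#'
#' @details Fields:
#' \describe{
#'   \item{dt}{integration time step, s (0.0002)}
#'   \item{tau_m, tau_syn}{membrane and synaptic time constants, s}
#'   \item{t_ax_delay}{axonal spike delay, s (0.003)}
#'   \item{t_ref}{refractory period, s (0.002)}
#'   \item{R_m}{membrane resistance, MOhm (10)}
#'   \item{V_rev, V_reset, V_th}{reversal, reset and threshold
#'     potentials, mV (-65, -70, -55)}
#'   \item{I_0}{mean background current, nA (0.15)}
#'   \item{sigma_wn}{background current white-noise scale, nA s^(1/2)}
#'   \item{N_e, N_i}{excitatory / inhibitory population sizes}
#'   \item{p_c}{connection probability (0.1)}
#'   \item{h_0}{baseline E-to-E weight, mV (4.20075)}
#'   \item{w_ei, w_ie, w_ii}{static coupling strengths, mV}
#'   \item{N_stim}{number of putative input neurons per stimulated cell}
#'   \item{f_recall}{recall stimulation frequency, Hz (100)}
#'   \item{r}{fraction of the assembly stimulated at recall (0.5)}
#'   \item{assembly_size}{number of neurons receiving the learning
#'     stimulus (150)}
#'   \item{t_c_delay}{delay of presynaptically evoked calcium, s}
#'   \item{c_pre, c_post}{calcium increments per pre-/postsynaptic spike}
#'   \item{tau_c}{calcium time constant, s (0.0488)}
#'   \item{tau_h}{early-phase weight time constant, s (688.4)}
#'   \item{gamma_p, gamma_d}{potentiation and depression rates}
#'   \item{theta_p, theta_d}{calcium thresholds for potentiation and
#'     depression (3, 1.2)}
#'   \item{sigma_pl}{early-phase plasticity noise scale, mV (2.90436)}
#'   \item{tau_p, tau_z}{protein and late-phase time constants, s (3600)}
#'   \item{alpha_p}{protein synthesis rate (1)}
#'   \item{theta_tag}{tagging threshold, mV (0.840149)}
#' }
#'
#' @return an object of class `stc_params` (a named list).
#' @examples
#' p <- model_params()
#' p$w_ei                      # 2 * 4.20075 mV
#' small <- model_params(N_e = 20, N_i = 5, assembly_size = 4)
#' @seealso [scaled_params()] for the reduced-size preset,
#'   [build_network()] for constructing a topology.
#' @export
model_params <- function(...) {
  defaults <- list(
    dt        = 0.0002,
    tau_m     = 0.010,
    tau_syn   = 0.005,
    t_ax_delay = 0.003,
    t_ref     = 0.002,
    R_m       = 10,
    V_rev     = -65,
    V_reset   = -70,
    V_th      = -55,
    I_0       = 0.15,
    sigma_wn  = 0.05,
    N_e       = 1600L,
    N_i       = 400L,
    p_c       = 0.1,
    h_0       = 4.20075,
    w_ei      = NA_real_,
    w_ie      = NA_real_,
    w_ii      = NA_real_,
    N_stim    = 4L,
    f_recall  = 100,
    r         = 0.5,
    assembly_size = 150L,
    t_c_delay = 0.0188,
    c_pre     = 0.6,
    c_post    = 0.1655,
    tau_c     = 0.0488,
    tau_h     = 688.4,
    gamma_p   = 1645.6,
    gamma_d   = 313.1,
    theta_p   = 3,
    theta_d   = 1.2,
    sigma_pl  = 2.90436,
    tau_p     = 3600,
    tau_z     = 3600,
    alpha_p   = 1,
    theta_tag = 0.840149
  )
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) && is.list(over[[1L]])) {
    over <- over[[1L]]
  }
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  p <- modifyList(defaults, over)
  # coupling strengths track h_0 unless given explicitly
  if (is.na(p$w_ei)) p$w_ei <- 2 * p$h_0
  if (is.na(p$w_ie)) p$w_ie <- 4 * p$h_0
  if (is.na(p$w_ii)) p$w_ii <- 4 * p$h_0
  p$N_e <- as.integer(p$N_e)
  p$N_i <- as.integer(p$N_i)
  p$N_stim <- as.integer(p$N_stim)
  p$assembly_size <- as.integer(p$assembly_size)
  class(p) <- "stc_params"
  validate_params(p)
  p
}

#' Validate model parameters
#'
#' Checks positivity of all time constants, rates and resistances, the
#' ordering of membrane potentials and calcium thresholds, and the
#' ranges of the probability-type parameters.
#'
#' @param p an `stc_params` object.
#' @return `p`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "stc_params"))
  pos <- c("dt", "tau_m", "tau_syn", "t_ax_delay", "t_ref", "R_m",
           "tau_c", "tau_h", "tau_p", "tau_z", "gamma_p", "gamma_d",
           "theta_p", "theta_d", "h_0", "t_c_delay", "c_pre", "c_post",
           "alpha_p", "theta_tag")
  for (nm in pos) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !(p[[nm]] > 0)) {
      stop("parameter '", nm, "' must be a single strictly positive number")
    }
  }
  nonneg <- c("sigma_wn", "sigma_pl", "f_recall", "I_0")
  for (nm in nonneg) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] < 0) {
      stop("parameter '", nm, "' must be a single non-negative number")
    }
  }
  if (!(p$V_reset < p$V_th)) stop("V_reset must be below V_th")
  if (!(p$theta_d < p$theta_p)) {
    stop("depression threshold theta_d must be below potentiation threshold theta_p")
  }
  if (!(p$p_c > 0 && p$p_c <= 1)) stop("p_c must be in (0, 1]")
  if (!(p$r > 0 && p$r <= 1)) stop("r must be in (0, 1]")
  if (p$N_e < 1L || p$N_i < 0L) stop("N_e must be >= 1 and N_i >= 0")
  if (p$assembly_size > p$N_e) {
    stop("assembly_size exceeds the excitatory population size N_e")
  }
  invisible(p)
}

#' Reduced-size parameter preset
#'
#' A network a quarter of the reference size (400 excitatory and 100
#' inhibitory neurons, assembly of 40, recall set of 20) intended for
#' desk-scale sweeps.  All synapse-level constants are unchanged; note
#' that the protein-synthesis sums scale with the assembly size, so the
#' absolute neuromodulator regimes shift relative to the full-size
#' network (see the methods vignette and [scaled_nm_levels()]).
#'
#' @param ... further overrides forwarded to [model_params()].
#' @return an `stc_params` object.
#' @export
scaled_params <- function(...) {
  model_params(N_e = 400L, N_i = 100L, assembly_size = 40L, ...)
}


#' @export
print.stc_params <- function(x, ...) {
  cat("Model parameters (stc_params)\n")
  cat(sprintf("  network: N_e=%d, N_i=%d, p_c=%g, assembly=%d, recall fraction r=%g\n",
              x$N_e, x$N_i, x$p_c, x$assembly_size, x$r))
  cat(sprintf("  neuron:  tau_m=%g ms, tau_syn=%g ms, t_ref=%g ms, V_th=%g mV, V_reset=%g mV\n",
              1e3 * x$tau_m, 1e3 * x$tau_syn, 1e3 * x$t_ref, x$V_th, x$V_reset))
  cat(sprintf("  weights: h_0=%g mV, w_ei=%g, w_ie=%g, w_ii=%g mV\n",
              x$h_0, x$w_ei, x$w_ie, x$w_ii))
  cat(sprintf("  plasticity: tau_h=%g s, tau_p=tau_z=%g s, theta_p=%g, theta_d=%g, theta_tag=%g mV\n",
              x$tau_h, x$tau_p, x$theta_p, x$theta_d, x$theta_tag))
  cat(sprintf("  integration: dt=%g ms\n", 1e3 * x$dt))
  invisible(x)
}
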