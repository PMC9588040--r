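#' Stimulation protocol timeline
#'
#' The standard protocol: activity settles for 10 s, then the learning
#' stimulus is applied to the core assembly as three 0.1 s pulses
#' separated by 0.4 s breaks (onsets 10.0, 10.5, 11.0 s).  A single
#' 0.1 s recall pulse at `f_recall` targets the recall subset either
#' 10 s or 8 h after the learning onset (recall onset 20.0 s or
#' 28810.0 s, so the rate-evaluation times are `t_recall` = 20.1 s or
#' 28810.1 s; `t_learn` = 11.0 s).  For the 8 h variant, spiking is
#' simulated until `ff_start` (0.5 s after the last pulse), the
#' consolidation gap is fast-forwarded, and spiking resumes
#' `resume_before` seconds before the recall pulse so that the
#' membrane, drive and PSP traces re-equilibrate.
#'
#' @param recall `"10s"` or `"8h"`.
#' @param learning_f learning stimulation frequency, Hz.
#' @param settle settling time before the first pulse, s.
#' @param pulse_dur,pulse_gap duration of and break between learning
#'   pulses, s.
#' @param n_pulses number of learning pulses.
#' @param ff_start time at which the consolidation fast-forward begins
#'   (8 h protocol), s.
#' @param resume_before seconds of spiking simulated before the recall
#'   pulse in the 8 h protocol.
#' @return an object of class `stc_timeline`.
#' @export
protocol_timeline <- function(recall = c("10s", "8h"), learning_f = 60,
                              settle = 10, pulse_dur = 0.1, pulse_gap = 0.4,
                              n_pulses = 3, ff_start = 11.6,
                              resume_before = 0.5) {
  recall <- match.arg(recall)
  stopifnot(learning_f >= 0, settle > 0, pulse_dur > 0, pulse_gap >= 0)
  onsets <- settle + (seq_len(n_pulses) - 1) * (pulse_dur + pulse_gap)
  pulses <- data.frame(onset = onsets, dur = pulse_dur)
  t_learn_end <- onsets[n_pulses] + pulse_dur
  recall_onset <- settle + if (recall == "10s") 10 else 28800
  if (recall == "8h" && ff_start <= t_learn_end) {
    stop("fast-forward must start after the learning stimulation ends")
  }
  tl <- list(
    recall = recall,
    learning_f = learning_f,
    settle = settle,
    pulses = pulses,
    t_learn = onsets[n_pulses],
    t_learn_end = t_learn_end,
    recall_onset = recall_onset,
    recall_dur = 0.1,
    t_recall = recall_onset + 0.1,
    t_end = recall_onset + 0.2,
    ff_start = ff_start,
    resume_at = recall_onset - resume_before
  )
  class(tl) <- "stc_timeline"
  tl
}

#' @export
print.stc_timeline <- function(x, ...) {
  cat(sprintf("stc_timeline (%s recall): settle %g s; %d learning pulses at %g Hz (%s s); recall pulse at %g s\n",
              x$recall, x$settle, nrow(x$pulses), x$learning_f,
              paste(x$pulses$onset, collapse = ", "), x$recall_onset))
  invisible(x)
}

# flat index structures handed to the C++ core (all 0-based)
.network_arrays <- function(topology) {
  p <- topology$params
  n <- p$N_e + p$N_i
  pre <- topology$pre
  post <- topology$post
  ee <- ee_synapses(topology)
  n_edge <- length(pre)
  out_syn <- rep.int(-1L, n_edge)
  out_syn[ee] <- seq_along(ee) - 1L
  cls_pre <- as.integer(topology$neuron_class[pre])   # 1=E, 2=I
  cls_post <- as.integer(topology$neuron_class[post])
  static_w <- numeric(n_edge)
  static_w[cls_pre == 1L & cls_post == 2L] <- p$w_ei
  static_w[cls_pre == 2L & cls_post == 1L] <- -p$w_ie
  static_w[cls_pre == 2L & cls_post == 2L] <- -p$w_ii
  syn_pre <- pre[ee]
  syn_post <- post[ee]
  list(
    out_ptr = c(0L, cumsum(tabulate(pre, n))),
    out_tgt = post - 1L,
    out_syn = out_syn,
    static_w = static_w,
    syn_pre = syn_pre - 1L,
    syn_post = syn_post - 1L,
    pre_ptr = c(0L, cumsum(tabulate(syn_pre, n))),
    pre_syn = seq_along(ee) - 1L,              # edges are pre-major sorted
    post_ptr = c(0L, cumsum(tabulate(syn_post, p$N_e))),
    post_syn = order(syn_post) - 1L,
    assembly = topology$assembly_ids - 1L,
    n_syn = length(ee)
  )
}

.initial_state <- function(params, n_syn) {
  n <- params$N_e + params$N_i
  list(V = rep(params$V_rev, n), V_bg = numeric(n), V_stim = numeric(n),
       psp = numeric(n), refrac = integer(n),
       h = rep(params$h_0, n_syn), z = numeric(n_syn), c = numeric(n_syn),
       p = numeric(params$N_e))
}

.config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f)
  unname(tools::md5sum(f))
}

#' Run a full learning/recall experiment
#'
#' Simulates the settle and learning phases, then either continues
#' spiking through a recall 10 s after learning onset, or
#' fast-forwards the consolidation gap and resumes spiking around a
#' recall 8 h later.  The learning pulses drive the core assembly at
#' `timeline$learning_f`; the recall pulse drives the recall subset at
#' `params$f_recall`.  All randomness (drive noise, plasticity noise)
#' derives from `seed`, so identical arguments give bit-identical
#' results.
#'
#' @param params an `stc_params` object (must match the topology's).
#' @param topology an `stc_topology` from [build_network()].
#' @param nm an `stc_nm` neuromodulator schedule.
#' @param recall `"10s"` or `"8h"`.
#' @param seed integer RNG seed for the run.
#' @param learning_f learning stimulation frequency, Hz (ignored if
#'   `timeline` is supplied).
#' @param timeline an `stc_timeline`; built from `recall` and
#'   `learning_f` if `NULL`.
#' @param dt_ff coarse step of the consolidation fast-forward, s.
#' @param record_neurons neuron ids (1-based) whose membrane potential
#'   and PSP trace are recorded every step.
#' @return an object of class `stc_run`: spike raster (`raster`),
#'   weight/protein snapshots (`snapshots$post_learning`,
#'   `$pre_recall`, `$post_recall`, each with `t`, `h`, `z`, `p`),
#'   protein/neuromodulator trace (`protein_trace`), recorded traces,
#'   final state, timings, and the provenance fields `seed`,
#'   `config_hash`, `version`.
#' @export
run_experiment <- function(params, topology, nm = nm_constant(0),
                           recall = c("10s", "8h"), seed,
                           learning_f = 60, timeline = NULL, dt_ff = 0.1,
                           record_neurons = integer(0)) {
  recall <- match.arg(recall)
  validate_params(params)
  stopifnot(inherits(topology, "stc_topology"), inherits(nm, "stc_nm"))
  if (!identical(params$N_e, topology$params$N_e) ||
      !identical(params$N_i, topology$params$N_i)) {
    stop("params network size does not match the topology")
  }
  if (is.null(timeline)) {
    timeline <- protocol_timeline(recall = recall, learning_f = learning_f)
  } else if (!identical(timeline$recall, recall)) {
    stop("timeline recall type does not match `recall`")
  }
  arr <- .network_arrays(topology)
  state <- .initial_state(params, arr$n_syn)
  set.seed(as.integer(seed))
  rec0 <- as.integer(record_neurons) - 1L
  pulses <- timeline$pulses
  n_p <- nrow(pulses)
  timings <- c()
  t_total <- proc.time()[["elapsed"]]

  if (recall == "10s") {
    res <- sim_spiking_cpp(
      arr, unclass(params), state, 0, timeline$t_end,
      stim_on = c(pulses$onset, timeline$recall_onset),
      stim_off = c(pulses$onset + pulses$dur,
                   timeline$recall_onset + timeline$recall_dur),
      stim_f = c(rep(timeline$learning_f, n_p), params$f_recall),
      stim_targets = c(rep(list(arr$assembly), n_p),
                       list(topology$recall_ids - 1L)),
      nm_breaks = nm$breaks, nm_levels = nm$levels,
      snapshot_times = c(timeline$t_learn_end, timeline$recall_onset,
                         timeline$t_end),
      record_neurons = rec0)
    spikes <- data.frame(neuron = res$spike_neuron, time = res$spike_time)
    snaps <- res$snapshots
    names(snaps) <- c("post_learning", "pre_recall", "post_recall")
    ptrace <- res$protein_trace
    windows <- data.frame(t0 = 0, t1 = timeline$t_end)
    traces <- list(V = res$trace_V, psp = res$trace_psp)
    state_final <- res$state
  } else {
    t1 <- proc.time()[["elapsed"]]
    res1 <- sim_spiking_cpp(
      arr, unclass(params), state, 0, timeline$ff_start,
      stim_on = pulses$onset, stim_off = pulses$onset + pulses$dur,
      stim_f = rep(timeline$learning_f, n_p),
      stim_targets = rep(list(arr$assembly), n_p),
      nm_breaks = nm$breaks, nm_levels = nm$levels,
      snapshot_times = timeline$t_learn_end,
      record_neurons = rec0)
    timings["learning"] <- proc.time()[["elapsed"]] - t1
    st <- res1$state
    t1 <- proc.time()[["elapsed"]]
    ff <- fast_forward_cpp(st$h, st$z, st$p, arr$syn_post, params$N_e,
                           timeline$ff_start, timeline$resume_at,
                           nm$breaks, nm$levels, dt_ff, unclass(params))
    timings["fast_forward"] <- proc.time()[["elapsed"]] - t1
    st2 <- .initial_state(params, arr$n_syn)
    st2$h <- ff$h; st2$z <- ff$z; st2$p <- ff$p
    t1 <- proc.time()[["elapsed"]]
    res2 <- sim_spiking_cpp(
      arr, unclass(params), st2, timeline$resume_at, timeline$t_end,
      stim_on = timeline$recall_onset,
      stim_off = timeline$recall_onset + timeline$recall_dur,
      stim_f = params$f_recall,
      stim_targets = list(topology$recall_ids - 1L),
      nm_breaks = nm$breaks, nm_levels = nm$levels,
      snapshot_times = c(timeline$recall_onset, timeline$t_end),
      record_neurons = rec0)
    timings["recall"] <- proc.time()[["elapsed"]] - t1
    spikes <- data.frame(
      neuron = c(res1$spike_neuron, res2$spike_neuron),
      time = c(res1$spike_time, res2$spike_time))
    snaps <- c(res1$snapshots, res2$snapshots)
    names(snaps) <- c("post_learning", "pre_recall", "post_recall")
    ptrace <- rbind(res1$protein_trace, res2$protein_trace)
    windows <- data.frame(t0 = c(0, timeline$resume_at),
                          t1 = c(timeline$ff_start, timeline$t_end))
    traces <- list(V_learning = res1$trace_V, psp_learning = res1$trace_psp,
                   V_recall = res2$trace_V, psp_recall = res2$trace_psp)
    state_final <- res2$state
  }
  timings["total"] <- proc.time()[["elapsed"]] - t_total

  n <- params$N_e + params$N_i
  raster <- spike_raster(spikes$neuron, spikes$time, n, windows)
  run <- list(
    raster = raster,
    snapshots = snaps,
    protein_trace = ptrace,
    traces = traces,
    state_final = state_final,
    params = params,
    timeline = timeline,
    nm = nm,
    recall = recall,
    seed = as.integer(seed),
    topology_seed = topology$seed,
    config_hash = .config_hash(list(unclass(params), unclass(timeline),
                                    unclass(nm), recall, seed,
                                    topology$seed)),
    version = as.character(utils::packageVersion("stcnet")),
    timings = timings
  )
  class(run) <- "stc_run"
  run
}

#' @export
print.stc_run <- function(x, ...) {
  cat("stc_run (", x$recall, " recall): ", nrow(x$raster), " spikes; seed ",
      x$seed, "; topology seed ", x$topology_seed, "\n", sep = "")
  cat("  learning_f =", x$timeline$learning_f, "Hz; NM level =",
      x$nm$level, "\n")
  invisible(x)
}

#' Per-class weight statistics from a run snapshot
#'
#' Mean early-phase, late-phase, and total weight (as percent of
#' baseline) of each synapse class at a snapshot time.
#'
#' @param run an `stc_run` object.
#' @param topology the topology the run was produced with.
#' @param snapshot which snapshot: `"post_learning"`, `"pre_recall"`
#'   or `"post_recall"`.
#' @return data.frame with one row per synapse class.
#' @export
weight_stats <- function(run, topology,
                         snapshot = c("pre_recall", "post_learning",
                                      "post_recall")) {
  snapshot <- match.arg(snapshot)
  sn <- run$snapshots[[snapshot]]
  cls <- classify_synapses(topology)
  tw <- total_weight(sn$h, sn$z, run$params)
  out <- do.call(rbind, lapply(levels(cls), function(cl) {
    i <- cls == cl
    data.frame(class = cl, n = sum(i),
               mean_h = mean(sn$h[i]), mean_z = mean(sn$z[i]),
               mean_percent = mean(tw$percent[i]),
               frac_late = mean(sn$z[i] > 0.5))
  }))
  out$t <- sn$t
  out
}

#' Standard metrics of a run
#'
#' Computes the analysis-suite metrics for one experiment: the
#' pattern-completion coefficient Q and the rate-distribution mutual
#' information at `t_recall` (rates from a trailing 0.5 s window), the
#' PCA dimensionality of the 1 ms-binned recall raster, the spike-time
#' stability between the final learning pulse and the recall pulse
#' (with a shuffled control), and the ridge-readout goodness of fit on
#' the recall segment.
#'
#' @param run an `stc_run` object.
#' @param topology the topology the run was produced with.
#' @param metrics subset of `c("Q", "MI", "pca", "stability",
#'   "readout")`.
#' @param bin_width bin width for the PCA / stability / readout
#'   rasters, s.
#' @param variance_fraction PCA explained-variance criterion.
#' @param p_out readout subsampling fraction.
#' @param n_targets number of random-walk targets averaged for the
#'   readout score.
#' @param alpha_ridge ridge penalty.
#' @param pool readout neuron pool: `"all"`, `"core"`, `"noncore"`.
#' @return one-row data.frame of metric values.
#' @export
run_metrics <- function(run, topology,
                        metrics = c("Q", "MI", "pca", "stability", "readout"),
                        bin_width = 0.001, variance_fraction = 0.7,
                        p_out = 0.5, n_targets = 3, alpha_ridge = 0.1,
                        pool = "all") {
  tl <- run$timeline
  p <- run$params
  out <- data.frame(recall = run$recall, seed = run$seed,
                    nm_level = run$nm$level, learning_f = tl$learning_f)
  exc <- seq_len(p$N_e)
  assembly <- topology$assembly_ids
  rec_ids <- topology$recall_ids
  if (any(c("Q", "MI") %in% metrics)) {
    nu_recall <- sliding_rate(run$raster, tl$t_recall)
  }
  if ("Q" %in% metrics) {
    out$Q <- pattern_completion_q(
      nu_recall, as_ids = rec_ids, ans_ids = setdiff(assembly, rec_ids),
      ctrl_ids = setdiff(exc, assembly))
  }
  if ("MI" %in% metrics) {
    nu_learn <- sliding_rate(run$raster, tl$t_learn)
    out$MI <- rate_mutual_information(nu_learn[exc], nu_recall[exc])
  }
  need_bins <- any(c("pca", "stability", "readout") %in% metrics)
  if (need_bins) {
    recall_bins <- bin_raster(run$raster, bin_width,
                              c(tl$recall_onset,
                                tl$recall_onset + tl$recall_dur))[exc, ,
                                                                  drop = FALSE]
  }
  if ("pca" %in% metrics) {
    out$pca_dim <- pca_dimensionality(recall_bins, variance_fraction)
  }
  if ("stability" %in% metrics) {
    learn_bins <- bin_raster(run$raster, bin_width,
                             c(tl$t_learn, tl$t_learn_end))[exc, ,
                                                            drop = FALSE]
    out$stability <- spike_time_stability(learn_bins, recall_bins)
    sh_seed <- run$seed + 7919L
    out$stability_shuffled <- spike_time_stability(
      shuffle_raster(learn_bins, seed = sh_seed),
      shuffle_raster(recall_bins, seed = sh_seed + 1L))
  }
  if ("readout" %in% metrics) {
    pulse_bins <- lapply(seq_len(nrow(tl$pulses)), function(i) {
      bin_raster(run$raster, bin_width,
                 c(tl$pulses$onset[i],
                   tl$pulses$onset[i] + tl$pulses$dur[i]))[exc, , drop = FALSE]
    })
    pool_ids <- switch(pool,
                       all = exc,
                       core = assembly,
                       noncore = setdiff(exc, assembly))
    r2 <- vapply(seq_len(n_targets), function(k) {
      tgt <- gaussian_random_walk(ncol(recall_bins), seed = run$seed + k)
      fit_ridge_readout(c(pulse_bins, list(recall_bins)), tgt,
                        p_out = p_out, neuron_pool = pool_ids,
                        alpha_ridge = alpha_ridge,
                        seed = run$seed + 100L + k)$r2
    }, numeric(1))
    out$readout_r2 <- mean(r2)
  }
  out
}

#' Parameter sweep over stimulation and neuromodulation conditions
#'
#' Runs the full protocol for every row of `grid` on `n_networks`
#' independently generated networks and collects the run metrics plus
#' per-class weight statistics.  Network `k` uses topology/run seed
#' `base_seed + k - 1`, so runs in different grid cells share networks
#' and learning-phase noise, pairing the conditions.
#'
#' @param params an `stc_params` object.
#' @param grid data.frame with any of the columns `learning_f`,
#'   `nm_level`, `onset_min`, `duration_min` (missing columns take the
#'   defaults 60 Hz, 0, 0, Inf); `duration_min` may be `Inf` for a
#'   schedule lasting the whole simulation, and `onset_min = 0,
#'   duration_min = Inf` with `constant_nm = TRUE` uses a schedule
#'   that is constant from `t = 0`.
#' @param n_networks number of network realisations per cell.
#' @param base_seed seed of the first network.
#' @param recall `"10s"` or `"8h"`.
#' @param constant_nm if `TRUE` (default) cells with `onset_min = 0`
#'   and infinite duration use [nm_constant()]; otherwise
#'   [nm_schedule()].
#' @param ... further arguments passed to [run_metrics()].
#' @return data.frame with one row per (grid cell, network).
#' @export
sweep_experiments <- function(params, grid, n_networks, base_seed,
                              recall = c("10s", "8h"), constant_nm = TRUE,
                              ...) {
  recall <- match.arg(recall)
  if (is.null(grid$learning_f)) grid$learning_f <- 60
  if (is.null(grid$nm_level)) grid$nm_level <- 0
  if (is.null(grid$onset_min)) grid$onset_min <- 0
  if (is.null(grid$duration_min)) grid$duration_min <- Inf
  rows <- list()
  for (net in seq_len(n_networks)) {
    seed <- as.integer(base_seed + net - 1L)
    topo <- build_network(params, seed = seed)
    for (g in seq_len(nrow(grid))) {
      nm <- if (constant_nm && grid$onset_min[g] == 0 &&
                is.infinite(grid$duration_min[g])) {
        nm_constant(grid$nm_level[g])
      } else {
        nm_schedule(grid$nm_level[g], grid$onset_min[g],
                    grid$duration_min[g])
      }
      run <- run_experiment(params, topo, nm = nm, recall = recall,
                            seed = seed, learning_f = grid$learning_f[g])
      m <- run_metrics(run, topo, ...)
      m$network <- net
      m$onset_min <- grid$onset_min[g]
      m$duration_min <- grid$duration_min[g]
      ws <- weight_stats(run, topo, "pre_recall")
      for (cl in ws$class) {
        m[[paste0("wpct_", cl)]] <- ws$mean_percent[ws$class == cl]
        m[[paste0("z_", cl)]] <- ws$mean_z[ws$class == cl]
      }
      rows[[length(rows) + 1L]] <- m
    }
  }
  do.call(rbind, rows)
}

#' Per-neuron sum of early-phase weight changes
#'
#' The quantity compared against the protein synthesis threshold:
#' for every excitatory neuron, the sum of `|h - h_0|` over its
#' incoming plastic synapses.
#'
#' @param topology an `stc_topology`.
#' @param h per-synapse early-phase weights in E-to-E edge order.
#' @param params an `stc_params` object.
#' @return numeric vector of length `N_e`, mV.
#' @export
early_change_sums <- function(topology, h, params) {
  ee <- ee_synapses(topology)
  stopifnot(length(h) == length(ee))
  s <- numeric(params$N_e)
  agg <- tapply(abs(h - params$h_0), topology$post[ee], sum)
  s[as.integer(names(agg))] <- agg
  s
}

#' Calibrate none/low/moderate/high neuromodulator levels
#'
#' The protein synthesis threshold `1/(NM + 0.001)` is compared
#' against the per-neuron sum of early-phase changes, which scales
#' with the network and assembly size; concentrations that realise the
#' none / low / moderate / high consolidation regimes therefore shift
#' when the network is scaled down.  This helper runs the learning
#' phase once (the neuromodulator level does not influence it),
#' measures the post-learning distribution of the protein-relevant
#' sums in core and non-core neurons, and places the thresholds by a
#' fixed rule: `low` between the core and non-core sums (geometric
#' mean of the core 10% quantile and the non-core median, so that
#' mostly core neurons synthesize proteins), `moderate` at the
#' non-core median, and `high` at the non-core 10% quantile (nearly
#' all neurons synthesize).  `none` is always 0.
#'
#' @param params an `stc_params` object.
#' @param seed seed for the calibration network and run.
#' @param learning_f learning stimulation frequency, Hz.
#' @return named numeric vector `c(none, low, moderate, high)` of
#'   neuromodulator concentrations, with the measured sum quantiles
#'   attached as attribute `"sums"`.
#' @export
calibrate_nm_levels <- function(params, seed = 1, learning_f = 60) {
  topo <- build_network(params, seed = seed)
  arr <- .network_arrays(topo)
  state <- .initial_state(params, arr$n_syn)
  tl <- protocol_timeline("8h", learning_f = learning_f)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  res <- sim_spiking_cpp(
    arr, unclass(params), state, 0, tl$ff_start,
    stim_on = tl$pulses$onset, stim_off = tl$pulses$onset + tl$pulses$dur,
    stim_f = rep(learning_f, nrow(tl$pulses)),
    stim_targets = rep(list(arr$assembly), nrow(tl$pulses)),
    nm_breaks = 0, nm_levels = 0,
    snapshot_times = tl$t_learn_end, record_neurons = integer(0))
  S <- early_change_sums(topo, res$snapshots[[1]]$h, params)
  core <- topo$assembly_ids
  s_core_q10 <- quantile(S[core], 0.1, names = FALSE)
  s_non_med <- quantile(S[-core], 0.5, names = FALSE)
  s_non_q10 <- quantile(S[-core], 0.1, names = FALSE)
  level <- function(theta) max(1 / theta - 0.001, 0)
  out <- c(none = 0,
           low = level(sqrt(s_core_q10 * s_non_med)),
           moderate = level(s_non_med),
           high = level(s_non_q10))
  attr(out, "sums") <- c(core_q10 = s_core_q10, noncore_median = s_non_med,
                         noncore_q10 = s_non_q10)
  out
}

#' Neuromodulator-timing experiment
#'
#' Crosses neuromodulation onset times with durations at a fixed level
#' and runs the 8 h protocol for each combination.  A duration of
#' `Inf` reproduces the always-on condition.
#'
#' @param params an `stc_params` object.
#' @param level neuromodulator concentration.
#' @param onsets_min onset times, minutes after the end of learning.
#' @param durations_min durations in minutes (may include `Inf`).
#' @param n_networks,base_seed as in [sweep_experiments()].
#' @param learning_f learning stimulation frequency, Hz.
#' @param ... passed to [run_metrics()].
#' @return data.frame as from [sweep_experiments()].
#' @export
nm_timing_experiment <- function(params, level, onsets_min, durations_min,
                                 n_networks, base_seed, learning_f = 60,
                                 ...) {
  grid <- expand.grid(onset_min = onsets_min, duration_min = durations_min)
  grid$nm_level <- level
  grid$learning_f <- learning_f
  sweep_experiments(params, grid, n_networks, base_seed, recall = "8h",
                    constant_nm = FALSE, ...)
}
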