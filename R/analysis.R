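#' Sliding-window firing rates
#'
#' The firing rate of every neuron at evaluation time `t_eval`: the
#' number of spikes in the trailing half-open window `(t_eval - window,
#' t_eval]` divided by the window length.  With the default 0.5 s
#' window the rates are non-negative multiples of 2 Hz.
#'
#' @param raster an `stc_raster` (or data.frame with `neuron`, `time`
#'   and an `n_neurons` attribute).
#' @param t_eval evaluation time, s.
#' @param window window length, s.
#' @return numeric vector of rates (Hz), one per neuron.
#' @export
sliding_rate <- function(raster, t_eval, window = 0.5) {
  n_neurons <- attr(raster, "n_neurons")
  if (is.null(n_neurons)) stop("raster lacks an n_neurons attribute")
  if (!raster_covers(raster, t_eval - window, t_eval)) {
    stop(sprintf("raster does not cover the window (%g, %g]",
                 t_eval - window, t_eval))
  }
  sel <- raster$time > t_eval - window & raster$time <= t_eval
  tabulate(raster$neuron[sel], n_neurons) / window
}

#' Pattern-completion coefficient Q
#'
#' Quantifies completion of the input-defined pattern at recall:
#' `Q = (nu_ans - nu_ctrl) / nu_as`, where `nu_as` is the mean rate of
#' assembly neurons stimulated at both learning and recall, `nu_ans`
#' of assembly neurons stimulated only at learning, and `nu_ctrl` of
#' control neurons stimulated at neither.  `Q = 1` is perfect
#' completion, `Q = 0` no completion.
#'
#' @param rates per-neuron rate vector (Hz), e.g. from
#'   [sliding_rate()].
#' @param as_ids,ans_ids,ctrl_ids neuron id vectors of the three
#'   subpopulations.
#' @return Q, or `NA` (with a warning) if the stimulated-assembly mean
#'   rate is zero.
#' @examples
#' pattern_completion_q(c(10, 10, 6, 6, 2, 2), 1:2, 3:4, 5:6)  # 0.4
#' @export
pattern_completion_q <- function(rates, as_ids, ans_ids, ctrl_ids) {
  nu_as <- mean(rates[as_ids])
  if (!is.finite(nu_as) || nu_as == 0) {
    warning("mean rate of the recall-stimulated subpopulation is zero; Q undefined")
    return(NA_real_)
  }
  (mean(rates[ans_ids]) - mean(rates[ctrl_ids])) / nu_as
}

# plug-in entropy (bits) of a discrete sample
.entropy <- function(x) {
  p <- table(x)
  p <- p / sum(p)
  -sum(p * log2(p))
}

#' Mutual information between firing-rate distributions
#'
#' Plug-in mutual information (bits) between the per-neuron rate
#' values at learning and at recall:
#' `MI = H(nu_learn) + H(nu_recall) - H(nu_learn, nu_recall)`,
#' computed from the empirical (joint) histogram over the exact
#' discrete rate values; rates from a 0.5 s count window are multiples
#' of 2 Hz, so no additional binning is applied.
#'
#' @param rates_learn,rates_recall per-neuron rate vectors over the
#'   same neuron set.
#' @return mutual information in bits (>= 0).
#' @export
rate_mutual_information <- function(rates_learn, rates_recall) {
  if (length(rates_learn) != length(rates_recall)) {
    stop("rate vectors must cover the same neurons")
  }
  .entropy(rates_learn) + .entropy(rates_recall) -
    .entropy(paste(rates_learn, rates_recall, sep = "\r"))
}

#' PCA dimensionality of a binned raster
#'
#' The number of principal components required to retain a given
#' fraction of the variance of the binned spike matrix.  Rows are
#' treated as samples (neurons) and columns as features (time bins),
#' i.e. the covariance is over time-bin features, matching a raster of
#' shape (neurons x bins); set `neurons_as_samples = FALSE` for the
#' transposed orientation.
#'
#' @param mat numeric matrix (neurons x time bins).
#' @param variance_fraction fraction of variance to retain (0.7).
#' @param neurons_as_samples orientation switch (see above).
#' @return integer: the smallest number of components whose cumulative
#'   explained variance reaches the requested fraction (0 for a matrix
#'   with no variance).
#' @export
pca_dimensionality <- function(mat, variance_fraction = 0.7,
                               neurons_as_samples = TRUE) {
  stopifnot(is.matrix(mat), variance_fraction > 0, variance_fraction <= 1)
  if (!neurons_as_samples) mat <- t(mat)
  cmat <- scale(mat, center = TRUE, scale = FALSE)
  if (all(abs(cmat) < 1e-12)) return(0L)
  sv <- svd(cmat, nu = 0, nv = 0)$d
  ev <- sv^2
  ev <- ev / sum(ev)
  as.integer(which(cumsum(ev) >= variance_fraction - 1e-12)[1])
}

#' Spike-time stability between learning and recall
#'
#' For each neuron, the number of 1 ms bins containing a spike during
#' both the final learning pulse and the recall pulse, divided by the
#' neuron's number of learning-pulse spike bins.  Neurons without any
#' learning-pulse spike have no score and are excluded from the
#' network average.
#'
#' @param learn_bins,recall_bins binary matrices (neurons x bins) with
#'   identical dimensions, e.g. from [bin_raster()] at 1 ms.
#' @param per_neuron if `TRUE`, return the per-neuron score vector
#'   (`NA` for zero-spike neurons) instead of the network mean.
#' @return network-mean stability score in [0, 1], or the per-neuron
#'   vector.
#' @export
spike_time_stability <- function(learn_bins, recall_bins,
                                 per_neuron = FALSE) {
  stopifnot(identical(dim(learn_bins), dim(recall_bins)))
  n_learn <- rowSums(learn_bins != 0)
  matches <- rowSums((learn_bins != 0) & (recall_bins != 0))
  score <- ifelse(n_learn > 0, matches / n_learn, NA_real_)
  if (per_neuron) return(score)
  if (all(is.na(score))) return(NA_real_)
  mean(score, na.rm = TRUE)
}

#' Shuffle the time bins of a binned raster
#'
#' Applies an independent uniform permutation of the bin indices to
#' each neuron (row), preserving per-neuron spike counts while
#' destroying temporal structure.  Used as the control condition for
#' [spike_time_stability()]; learning and recall rasters are shuffled
#' independently.
#'
#' @param bins binary matrix (neurons x bins).
#' @param seed optional RNG seed for the permutations.
#' @return shuffled matrix of the same dimensions.
#' @export
shuffle_raster <- function(bins, seed = NULL) {
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
  }
  out <- bins
  nb <- ncol(bins)
  for (i in seq_len(nrow(bins))) {
    out[i, ] <- bins[i, sample.int(nb)]
  }
  out
}

#' Correlation between spike-time stability and core input strength
#'
#' Spearman rank correlation (with tie handling) between per-neuron
#' spike-time stability and the mean late-phase synaptic weight each
#' neuron receives from the core assembly.  Neurons without a defined
#' stability score are excluded.
#'
#' @param stability per-neuron stability scores (may contain `NA`).
#' @param core_weight per-neuron mean late-phase weight received from
#'   the core assembly.
#' @return Spearman's rho.
#' @export
stability_weight_correlation <- function(stability, core_weight) {
  stopifnot(length(stability) == length(core_weight))
  ok <- is.finite(stability) & is.finite(core_weight)
  if (sum(ok) < 3) stop("fewer than 3 neurons with defined stability scores")
  cor(stability[ok], core_weight[ok], method = "spearman")
}

#' Gaussian random-walk target sequence
#'
#' `y[1] = y0`, `y[i+1] = y[i] + N(0, 1)`: the arbitrary temporal
#' target that the linear readout is trained to produce.
#'
#' @param length sequence length (number of 1 ms bins).
#' @param y0 initial value.
#' @param seed optional RNG seed.
#' @return numeric vector of length `length`.
#' @export
gaussian_random_walk <- function(length = 100, y0 = 1, seed = NULL) {
  stopifnot(length >= 1)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
  }
  y0 + c(0, cumsum(rnorm(length - 1)))
}

#' Ridge-regression readout of temporal sequences
#'
#' Trains a linear readout `w` minimising
#' `||y - X w||^2 + alpha ||w||^2` on the concatenated 1 ms-binned
#' rasters of the three learning pulses and the recall pulse (rows:
#' 4 x 100 time bins; columns: a subsample of the neuron pool plus an
#' intercept column, which is penalised together with the rest, as in
#' the stated objective).  The target sequence is repeated for each
#' segment.  The fitted readout is then evaluated on the recall
#' segment alone, returning the coefficient of determination.
#'
#' @param segments list of binned rasters (neurons x bins), ordered
#'   pulse 1..3 then recall; all with the same dimensions.
#' @param target target sequence, one value per bin of a segment.
#' @param p_out fraction of the pool to sample (without replacement);
#'   the subsample size is `round(p_out * length(neuron_pool))`.
#' @param neuron_pool neuron ids (row indices) eligible for sampling.
#' @param alpha_ridge ridge penalty (default 0.1).
#' @param seed optional RNG seed for the subsample.
#' @return list with `weights` (including the trailing intercept
#'   weight), `r2` on the recall segment, and `neurons` (the sampled
#'   ids).
#' @export
fit_ridge_readout <- function(segments, target, p_out = 1,
                              neuron_pool = seq_len(nrow(segments[[1]])),
                              alpha_ridge = 0.1, seed = NULL) {
  stopifnot(is.list(segments), length(segments) >= 2)
  nb <- ncol(segments[[1]])
  stopifnot(length(target) == nb)
  k <- round(p_out * length(neuron_pool))
  if (k < 1) stop("empty readout subsample")
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
  }
  ids <- if (k == length(neuron_pool)) neuron_pool else
    sort(sample(neuron_pool, k))
  X <- do.call(rbind, lapply(segments, function(m) t(m[ids, , drop = FALSE])))
  X <- cbind(X, 1)                       # intercept column, penalised too
  y <- rep(target, length(segments))
  A <- crossprod(X)
  diag(A) <- diag(A) + alpha_ridge
  w <- solve(A, crossprod(X, y))
  n_recall <- nrow(X) - nb
  Xr <- X[(n_recall + 1):nrow(X), , drop = FALSE]
  pred <- as.numeric(Xr %*% w)
  ss_res <- sum((target - pred)^2)
  ss_tot <- sum((target - mean(target))^2)
  list(weights = as.numeric(w), r2 = 1 - ss_res / ss_tot,
       neurons = ids)
}

#' Readout performance across output connectivities
#'
#' Mean ridge-readout goodness of fit as a function of the fraction of
#' sampled output neurons, averaged over several random-walk targets,
#' for one or more neuron pools.
#'
#' @param segments list of binned rasters as in [fit_ridge_readout()].
#' @param p_out_grid fractions to evaluate (default 0.1 .. 1.0).
#' @param n_targets number of random-walk targets (default 10).
#' @param pools named list of neuron-id vectors (e.g. all / core /
#'   non-core).
#' @param alpha_ridge ridge penalty.
#' @param seed base RNG seed; targets and subsamples are derived from
#'   it deterministically.
#' @return data.frame with columns `pool`, `p_out`, `r2` (mean over
#'   targets) and `r2_sd`.
#' @export
readout_connectivity_curve <- function(segments,
                                       p_out_grid = seq(0.1, 1, by = 0.1),
                                       n_targets = 10,
                                       pools = list(all = seq_len(nrow(segments[[1]]))),
                                       alpha_ridge = 0.1, seed = 1) {
  nb <- ncol(segments[[1]])
  targets <- lapply(seq_len(n_targets), function(k) {
    gaussian_random_walk(nb, seed = seed + k)
  })
  rows <- list()
  for (pn in names(pools)) {
    for (p_out in p_out_grid) {
      r2 <- vapply(seq_len(n_targets), function(k) {
        fit_ridge_readout(segments, targets[[k]], p_out = p_out,
                          neuron_pool = pools[[pn]],
                          alpha_ridge = alpha_ridge,
                          seed = seed + 1000L * match(pn, names(pools)) +
                            10000L * round(100 * p_out) + k)$r2
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        pool = pn, p_out = p_out, r2 = mean(r2), r2_sd = sd(r2))
    }
  }
  do.call(rbind, rows)
}

#' Mean late-phase weight received from the core assembly
#'
#' For every excitatory neuron outside the core assembly, the mean
#' late-phase weight of the synapses it receives from core neurons
#' (`NA` for neurons receiving none).  Companion quantity to the
#' per-neuron spike-time stability.
#'
#' @param topology an `stc_topology`.
#' @param z per-synapse late-phase weights in E-to-E edge order (e.g.
#'   from a run snapshot).
#' @return numeric vector over all excitatory neurons (`NA` for core
#'   neurons and for neurons without core input).
#' @export
core_input_weight <- function(topology, z) {
  ee <- ee_synapses(topology)
  pre <- topology$pre[ee]
  post <- topology$post[ee]
  stopifnot(length(z) == length(ee))
  n_e <- topology$params$N_e
  sel <- pre %in% topology$assembly_ids & !(post %in% topology$assembly_ids)
  sums <- tapply(z[sel], post[sel], mean)
  out <- rep(NA_real_, n_e)
  out[as.integer(names(sums))] <- as.numeric(sums)
  out
}
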