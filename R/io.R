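#' Load and save experiment configurations
#'
#' A configuration is a YAML (or JSON) file with up to four top-level
#' sections: `params` (model constants, see [model_params()]),
#' `protocol` (`recall`, `learning_f`, and optionally the timeline
#' fields of [protocol_timeline()]), `nm` (`level`, `onset_min`,
#' `duration_min` -- `duration_min: max` means always-on; `constant:
#' true` requests a level held from `t = 0`) and `seed`.  Unspecified
#' keys take the package defaults; unknown keys raise an error so that
#' typos never pass silently.
#'
#' @param path file path (`.yaml`/`.yml`/`.json`).
#' @return list with elements `params` (`stc_params`), `timeline`
#'   (`stc_timeline`), `nm` (`stc_nm`) and `seed`.
#' @export
load_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), c("params", "protocol", "nm", "seed"))
  if (length(unknown)) {
    stop("unknown configuration section(s): ", paste(unknown, collapse = ", "))
  }
  params <- do.call(model_params, as.list(cfg$params))
  proto <- as.list(cfg$protocol)
  allowed <- c("recall", "learning_f", "settle", "pulse_dur", "pulse_gap",
               "n_pulses", "ff_start", "resume_before")
  unknown <- setdiff(names(proto), allowed)
  if (length(unknown)) {
    stop("unknown protocol key(s): ", paste(unknown, collapse = ", "))
  }
  timeline <- do.call(protocol_timeline, proto)
  nm_cfg <- as.list(cfg$nm)
  unknown <- setdiff(names(nm_cfg), c("level", "onset_min", "duration_min",
                                      "constant"))
  if (length(unknown)) {
    stop("unknown nm key(s): ", paste(unknown, collapse = ", "))
  }
  level <- if (is.null(nm_cfg$level)) 0 else nm_cfg$level
  nm <- if (isTRUE(nm_cfg$constant)) {
    nm_constant(level)
  } else {
    dur <- nm_cfg$duration_min
    if (is.null(dur)) dur <- Inf
    nm_schedule(level,
                onset_min = if (is.null(nm_cfg$onset_min)) 0 else nm_cfg$onset_min,
                duration_min = dur,
                t_learn_end = timeline$t_learn_end)
  }
  list(params = params, timeline = timeline, nm = nm,
       seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed))
}

#' @rdname load_config
#' @param config a list as returned by [load_config()] (or with the
#'   same sections).
#' @export
save_config <- function(config, path) {
  tl <- config$timeline
  nm <- config$nm
  out <- list(
    params = unclass(config$params),
    protocol = list(recall = tl$recall, learning_f = tl$learning_f,
                    settle = tl$settle, pulse_dur = tl$pulses$dur[1],
                    pulse_gap = if (nrow(tl$pulses) > 1)
                      tl$pulses$onset[2] - tl$pulses$onset[1] - tl$pulses$dur[1]
                    else 0.4,
                    n_pulses = nrow(tl$pulses), ff_start = tl$ff_start),
    nm = list(level = nm$level,
              onset_min = nm$onset_min,
              duration_min = if (is.infinite(nm$duration_min)) "max"
                             else nm$duration_min,
              constant = length(nm$levels) == 1L),
    seed = config$seed
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Spike raster TSV serialization
#'
#' Writes a raster as a two-column TSV (`time_s`, `neuron_id`); the
#' header comment records the population size and the covered windows
#' so that the raster round-trips.  Neuron ids are 1-based with the
#' excitatory block first.
#'
#' @param raster an `stc_raster`.
#' @param path file path.
#' @return the path, invisibly (`write`), or the raster (`read`).
#' @export
write_raster_tsv <- function(raster, path) {
  w <- attr(raster, "windows")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# n_neurons=", attr(raster, "n_neurons")),
    paste0("# windows=", paste(sprintf("%.6f:%.6f", w$t0, w$t1),
                               collapse = ","))), con)
  write.table(data.frame(time_s = sprintf("%.6f", raster$time),
                         neuron_id = raster$neuron),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_raster_tsv
#' @export
read_raster_tsv <- function(path) {
  hdr <- readLines(path, n = 2)
  n_neurons <- as.integer(sub("# n_neurons=", "", hdr[1]))
  wspec <- strsplit(sub("# windows=", "", hdr[2]), ",")[[1]]
  wmat <- do.call(rbind, lapply(strsplit(wspec, ":"), as.numeric))
  df <- read.delim(path, skip = 2)
  spike_raster(df$neuron_id, df$time_s, n_neurons,
               windows = data.frame(t0 = wmat[, 1], t1 = wmat[, 2]))
}

#' Weight snapshot TSV serialization
#'
#' Writes a per-synapse weight table (`pre_id`, `post_id`, `h`, `z`,
#' `class`) with the snapshot time in the header comment.
#'
#' @param topology the `stc_topology` the snapshot belongs to.
#' @param snapshot a snapshot list with fields `t`, `h`, `z` (as in
#'   `stc_run$snapshots`).
#' @param path file path.
#' @export
write_weights_tsv <- function(topology, snapshot, path) {
  ee <- ee_synapses(topology)
  df <- data.frame(pre_id = topology$pre[ee], post_id = topology$post[ee],
                   h = snapshot$h, z = snapshot$z,
                   class = as.character(classify_synapses(topology)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# t=", snapshot$t), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weights_tsv
#' @export
read_weights_tsv <- function(path) {
  t_snap <- as.numeric(sub("# t=", "", readLines(path, n = 1)))
  df <- read.delim(path, skip = 1, stringsAsFactors = FALSE)
  attr(df, "t") <- t_snap
  df
}

#' Synthetic fixture generator for the analysis suite
#'
#' Generates paired "learning"/"recall" binned rasters and a labelled
#' weight table with controllable statistical structure, so that every
#' analysis operation can be exercised without running the simulator.
#' Each learning spike recurs at the same bin of the recall raster
#' with probability `overlap` and is otherwise relocated to a random
#' free bin (preserving per-neuron spike counts).  With `rank` set,
#' the two rasters are identical low-rank matrices: neurons share one
#' of `rank` random temporal profiles.
#'
#' @param n_neurons,n_bins raster dimensions.
#' @param rate per-neuron firing rate, Hz (with `bin_width` bins; at
#'   most one spike per bin, so `rate * bin_width` must be <= 1).
#' @param overlap probability that a learning spike recurs at the same
#'   recall bin, in [0, 1].
#' @param rank optional latent rank for PCA fixtures.
#' @param bin_width bin width, s.
#' @param n_core,n_total assembly / population sizes for the weight
#'   table.
#' @param p_c connection probability of the weight table.
#' @param frac_potentiated named fractions of late-phase-potentiated
#'   synapses per class (defaults 0 everywhere).
#' @param seed RNG seed.
#' @return list with `learn`, `recall` (binary matrices), `weights`
#'   (data.frame: pre, post, h, z, class) and the generating spec.
#' @export
generate_fixture <- function(n_neurons = 50, n_bins = 100, rate = 40,
                             overlap = 1, rank = NULL, bin_width = 0.001,
                             n_core = 10, n_total = n_neurons, p_c = 0.2,
                             frac_potentiated = c(core_internal = 0,
                                                  outgoing = 0,
                                                  incoming = 0,
                                                  control = 0),
                             seed = 1) {
  if (overlap < 0 || overlap > 1) stop("overlap must be in [0, 1]")
  p_bin <- rate * bin_width
  if (p_bin > 1) stop("infeasible rate: more than one spike per bin")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  if (!is.null(rank)) {
    if (rank > min(n_neurons, n_bins)) stop("rank exceeds matrix dimensions")
    # neurons share one of `rank` temporal profiles at neuron-specific
    # amplitudes, so the centered matrix keeps the full latent rank
    profiles <- matrix(rbinom(rank * n_bins, 1, 0.5), rank, n_bins)
    amp <- runif(n_neurons, 0.5, 1.5)
    learn <- amp * profiles[rep_len(seq_len(rank), n_neurons), , drop = FALSE]
    recall <- learn
  } else {
    learn <- matrix(rbinom(n_neurons * n_bins, 1, p_bin), n_neurons, n_bins)
    recall <- matrix(0L, n_neurons, n_bins)
    for (i in seq_len(n_neurons)) {
      spk <- which(learn[i, ] == 1)
      keep <- spk[runif(length(spk)) < overlap]
      n_move <- length(spk) - length(keep)
      free <- setdiff(seq_len(n_bins), keep)
      moved <- if (n_move > 0) sample(free, n_move) else integer(0)
      recall[i, c(keep, moved)] <- 1L
    }
  }
  # labelled weight table
  fp <- frac_potentiated
  for (cl in c("core_internal", "outgoing", "incoming", "control")) {
    if (is.na(fp[cl])) fp[cl] <- 0
  }
  pairs <- expand.grid(pre = seq_len(n_total), post = seq_len(n_total))
  pairs <- pairs[pairs$pre != pairs$post, ]
  pairs <- pairs[runif(nrow(pairs)) < p_c, ]
  core <- seq_len(n_core)
  cls <- ifelse(pairs$pre %in% core & pairs$post %in% core, "core_internal",
         ifelse(pairs$pre %in% core, "outgoing",
         ifelse(pairs$post %in% core, "incoming", "control")))
  h0 <- 4.20075
  z <- numeric(nrow(pairs))
  for (cl in unique(cls)) {
    i <- which(cls == cl)
    pot <- i[runif(length(i)) < fp[cl]]
    z[pot] <- runif(length(pot), 0.5, 1)
  }
  weights <- data.frame(pre = pairs$pre, post = pairs$post,
                        h = h0 + rnorm(nrow(pairs), 0, 0.05 * h0),
                        z = z, class = cls)
  list(learn = learn, recall = recall, weights = weights,
       spec = list(n_neurons = n_neurons, n_bins = n_bins, rate = rate,
                   overlap = overlap, rank = rank, seed = seed))
}

#' Run manifest
#'
#' A small JSON-serializable record that fully determines re-execution
#' of a run: configuration hash, seeds, package version, per-phase
#' wall times and the output file inventory.
#'
#' @param run an `stc_run`.
#' @param files named character vector of output paths.
#' @param path optional path; if given the manifest is written as JSON.
#' @return the manifest list, invisibly if written.
#' @export
run_manifest <- function(run, files = character(0), path = NULL) {
  m <- list(
    config_hash = run$config_hash,
    seed = run$seed,
    topology_seed = run$topology_seed,
    recall = run$recall,
    nm_level = run$nm$level,
    learning_f = run$timeline$learning_f,
    version = run$version,
    timings_s = as.list(run$timings),
    files = as.list(files)
  )
  if (!is.null(path)) {
    jsonlite::write_json(m, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    return(invisible(m))
  }
  m
}
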