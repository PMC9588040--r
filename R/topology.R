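#' Build a random network topology
#'
#' Draws a directed Erdos-Renyi topology over the `N_e + N_i` neurons:
#' every ordered pair (pre, post) with pre != post is connected
#' independently with probability `p_c`.  Neurons `1..N_e` are
#' excitatory, `N_e+1 .. N_e+N_i` inhibitory.  The core assembly is the
#' first `assembly_size` excitatory neurons and the recall set is the
#' first `round(r * assembly_size)` of those, matching the protocol in
#' which the learning stimulus targets the assembly and the recall
#' stimulus targets its first half.
#'
#' @param params an `stc_params` object.
#' @param seed integer RNG seed; the same seed always yields the same
#'   topology.
#' @return an object of class `stc_topology`: a list with the edge list
#'   (`pre`, `post`, 1-based), `neuron_class` (factor with levels
#'   `"E"`, `"I"`), `assembly_ids`, `recall_ids`, the generating `seed`
#'   and the `params` used.
#' @examples
#' topo <- build_network(model_params(N_e = 40, N_i = 10), seed = 1)
#' table(classify_synapses(topo))
#' @export
build_network <- function(params, seed) {
  validate_params(params)
  stopifnot(length(seed) == 1L, is.finite(seed))
  n <- params$N_e + params$N_i
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  pre <- vector("list", n)
  post <- vector("list", n)
  for (j in seq_len(n)) {
    u <- runif(n)
    tgt <- which(u < params$p_c)
    tgt <- tgt[tgt != j]
    post[[j]] <- tgt
    pre[[j]] <- rep.int(j, length(tgt))
  }
  pre <- unlist(pre, use.names = FALSE)
  post <- unlist(post, use.names = FALSE)
  neuron_class <- factor(rep(c("E", "I"), c(params$N_e, params$N_i)),
                         levels = c("E", "I"))
  n_recall <- as.integer(round(params$r * params$assembly_size))
  topo <- list(
    pre = as.integer(pre),
    post = as.integer(post),
    neuron_class = neuron_class,
    assembly_ids = seq_len(params$assembly_size),
    recall_ids = seq_len(n_recall),
    seed = as.integer(seed),
    params = params
  )
  class(topo) <- "stc_topology"
  topo
}

# save/restore the global RNG state so topology construction does not
# perturb a caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.stc_topology <- function(x, ...) {
  p <- x$params
  cat("stc_topology:", p$N_e, "excitatory +", p$N_i, "inhibitory neurons,",
      length(x$pre), "directed connections\n")
  cat("  assembly:", length(x$assembly_ids), "neurons; recall set:",
      length(x$recall_ids), "neurons; seed:", x$seed, "\n")
  invisible(x)
}

#' Indices of the excitatory-to-excitatory synapses
#'
#' @param topology an `stc_topology` object.
#' @return integer vector of positions into the topology edge list.
#' @export
ee_synapses <- function(topology) {
  which(topology$neuron_class[topology$pre] == "E" &
        topology$neuron_class[topology$post] == "E")
}

#' Classify plastic synapses by their relation to the core assembly
#'
#' Every excitatory-to-excitatory synapse falls into exactly one of
#' four classes: `core_internal` (both endpoints in the assembly),
#' `outgoing` (assembly to non-assembly; if consolidated, the
#' postsynaptic neurons act as support neurons), `incoming`
#' (non-assembly to assembly) and `control` (both endpoints outside the
#' assembly).
#'
#' @param topology an `stc_topology` object.
#' @return a factor of length `length(ee_synapses(topology))` with
#'   levels `core_internal`, `outgoing`, `incoming`, `control`, in the
#'   order of the E-to-E edges in the topology edge list.
#' @export
classify_synapses <- function(topology) {
  stopifnot(inherits(topology, "stc_topology"))
  ee <- ee_synapses(topology)
  pre_in <- topology$pre[ee] %in% topology$assembly_ids
  post_in <- topology$post[ee] %in% topology$assembly_ids
  cls <- ifelse(pre_in & post_in, "core_internal",
         ifelse(pre_in & !post_in, "outgoing",
         ifelse(!pre_in & post_in, "incoming", "control")))
  factor(cls, levels = c("core_internal", "outgoing", "incoming", "control"))
}

#' Static synaptic weight by pre/post neuron class
#'
#' Connections involving inhibitory neurons carry fixed weights:
#' E-to-I couples with `2 * h_0`, I-to-E and I-to-I with `4 * h_0`.
#' E-to-E synapses are plastic (early- plus late-phase weight, see
#' [total_weight()]); for those this function returns `NA`.
#'
#' @param pre_class,post_class character vectors of `"E"` / `"I"`.
#' @param params an `stc_params` object.
#' @return numeric vector of weight magnitudes in mV (`NA` for E-to-E).
#' @examples
#' static_weight("E", "I", model_params())   # 8.4015
#' @export
static_weight <- function(pre_class, post_class, params) {
  stopifnot(all(pre_class %in% c("E", "I")), all(post_class %in% c("E", "I")))
  n <- max(length(pre_class), length(post_class))
  pre_class <- rep_len(as.character(pre_class), n)
  post_class <- rep_len(as.character(post_class), n)
  w <- rep(NA_real_, n)
  w[pre_class == "E" & post_class == "I"] <- params$w_ei
  w[pre_class == "I" & post_class == "E"] <- params$w_ie
  w[pre_class == "I" & post_class == "I"] <- params$w_ii
  w
}

#' Write / read a topology edge list as TSV
#'
#' The table has columns `pre_id`, `post_id` (1-based) and `class`
#' (the synapse class for E-to-E edges, or `static` otherwise).
#'
#' @param topology an `stc_topology` object.
#' @param path file path.
#' @return `write_topology_tsv` returns `path` invisibly;
#'   `read_topology_tsv` returns the edge table as a data.frame.
#' @export
write_topology_tsv <- function(topology, path) {
  cls <- rep("static", length(topology$pre))
  ee <- ee_synapses(topology)
  cls[ee] <- as.character(classify_synapses(topology))
  df <- data.frame(pre_id = topology$pre, post_id = topology$post,
                   class = cls)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_topology_tsv
#' @export
read_topology_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
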