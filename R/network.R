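#' Connectivity specification for the random network
#'
#' Defaults describe the full-size network: 4000 regular-spiking (RS)
#' excitatory and 1000 fast-spiking (FS) inhibitory neurons, every ordered
#' pair connected independently with probability 0.1, plus two pools of
#' external Poisson spike trains (background drive and stimulus) of 5000
#' trains each wired to the neurons with the same probability.
#'
#' @param n_rs number of RS neurons.
#' @param n_fs number of FS neurons.
#' @param p recurrent connection probability per ordered pair.
#' @param n_ext number of external drive trains (also used for the
#'   stimulus pool).
#' @param p_ext external connection probability.
#' @param seed integer seed controlling the sampled wiring.
#'
#' @return An object of class `connectivity_spec`.
#' @export
connectivity_spec <- function(n_rs = 4000, n_fs = 1000, p = 0.1,
                              n_ext = 5000, p_ext = 0.1, seed = 1L) {
  stopifnot_scalar(n_rs, "n_rs", positive = TRUE)
  stopifnot_scalar(n_fs, "n_fs", positive = TRUE)
  stopifnot_scalar(n_ext, "n_ext", nonneg = TRUE)
  if (p < 0 || p > 1) stop("`p` must lie in [0, 1]", call. = FALSE)
  if (p_ext < 0 || p_ext > 1) stop("`p_ext` must lie in [0, 1]", call. = FALSE)
  structure(list(n_rs = as.integer(n_rs), n_fs = as.integer(n_fs), p = p,
                 n_ext = as.integer(n_ext), p_ext = p_ext,
                 seed = as.integer(seed)),
            class = "connectivity_spec")
}

# Sample out-neighbourhoods for `n_pre` sources over `n_post` targets with
# pairwise probability `p`. `skip_self` removes the diagonal (recurrent
# classes index the same neuron pool as their targets, offset by `offset`).
# Returns CSR-style list(ptr, tgt) with 1-based targets.
sample_adjacency <- function(n_pre, n_post, p, skip_self = FALSE,
                             offset = 0L) {
  ptr <- integer(n_pre + 1L)
  if (n_pre == 0L || p == 0) {
    return(list(ptr = ptr, tgt = integer(0)))
  }
  n_avail <- if (skip_self) n_post - 1L else n_post
  ks <- stats::rbinom(n_pre, n_avail, p)
  ptr[-1L] <- cumsum(ks)
  tgt <- integer(ptr[n_pre + 1L])
  for (pre in seq_len(n_pre)) {
    k <- ks[pre]
    if (k == 0L) next
    idx <- sample.int(n_avail, k)
    if (skip_self) {
      self <- pre + offset
      idx[idx >= self] <- idx[idx >= self] + 1L
    }
    tgt[(ptr[pre] + 1L):ptr[pre + 1L]] <- idx
  }
  list(ptr = ptr, tgt = tgt)
}

#' Build the random RS/FS network graph and external wiring
#'
#' Connects every ordered pair of distinct neurons independently with
#' probability `p` (one Bernoulli draw per pair, so in-degrees are
#' Binomial), and wires each external train (background pool and stimulus
#' pool separately) to each neuron with probability `p_ext`. The synapse
#' type is implied by the source class: RS spikes drive AMPA and NMDA,
#' FS spikes drive GABA-A, background drive spikes drive AMPA only, and
#' stimulus spikes drive both AMPA and NMDA. All edges share one
#' transmission delay.
#'
#' Neuron indexing is 1..n_rs for RS followed by n_rs+1..n_rs+n_fs for FS.
#'
#' @param spec a [connectivity_spec()].
#' @param delay synaptic delay (ms), applied uniformly.
#'
#' @return An object of class `network_graph` holding CSR adjacency
#'   (`ptr`/`tgt`) per source class (`rs`, `fs`, `ext`, `stim`).
#' @export
build_graph <- function(spec = connectivity_spec(), delay = 1.5) {
  stopifnot(inherits(spec, "connectivity_spec"))
  n <- spec$n_rs + spec$n_fs
  graph <- with_local_seed(derive_seed(spec$seed, "graph"), {
    rs <- sample_adjacency(spec$n_rs, n, spec$p, skip_self = TRUE,
                           offset = 0L)
    fs <- sample_adjacency(spec$n_fs, n, spec$p, skip_self = TRUE,
                           offset = spec$n_rs)
    ext <- sample_adjacency(spec$n_ext, n, spec$p_ext)
    stim <- sample_adjacency(spec$n_ext, n, spec$p_ext)
    list(rs = rs, fs = fs, ext = ext, stim = stim)
  })
  structure(c(graph,
              list(n_rs = spec$n_rs, n_fs = spec$n_fs, n_ext = spec$n_ext,
                   p = spec$p, p_ext = spec$p_ext, delay = delay,
                   seed = spec$seed)),
            class = "network_graph")
}

#' Degree summary of a network graph
#'
#' Per source class, reports the out-degree mean/SD over sources and the
#' in-degree mean/SD over all neurons. For the default network the
#' expected mean in-degrees are ~400 from RS sources, ~100 from FS
#' sources and ~500 from the external drive (n_source x p); the recurrent
#' excitatory plus external contacts together make up the ~500+400
#' excitatory synapses a neuron receives on average.
#'
#' @param graph a [build_graph()] result.
#'
#' @return A tibble with one row per source class.
#' @export
degree_report <- function(graph) {
  stopifnot(inherits(graph, "network_graph"))
  n <- graph$n_rs + graph$n_fs
  one <- function(adj, n_src, class) {
    out_deg <- diff(adj$ptr)
    in_deg <- tabulate(adj$tgt, nbins = n)
    tibble::tibble(source_class = class, n_sources = n_src,
                   n_edges = length(adj$tgt),
                   mean_out = if (n_src > 0) mean(out_deg) else 0,
                   sd_out = if (n_src > 1) stats::sd(out_deg) else 0,
                   mean_in = mean(in_deg), sd_in = stats::sd(in_deg))
  }
  rbind(one(graph$rs, graph$n_rs, "RS"),
        one(graph$fs, graph$n_fs, "FS"),
        one(graph$ext, graph$n_ext, "EXT"),
        one(graph$stim, graph$n_ext, "STIM"))
}

#' @export
print.network_graph <- function(x, ...) {
  cat(sprintf("Random network graph: %d RS + %d FS neurons (p = %g), %d external trains (p = %g)\n",
              x$n_rs, x$n_fs, x$p, x$n_ext, x$p_ext))
  cat(sprintf("  edges: RS %d, FS %d, EXT %d, STIM %d; delay %g ms; seed %d\n",
              length(x$rs$tgt), length(x$fs$tgt), length(x$ext$tgt),
              length(x$stim$tgt), x$delay, x$seed))
  invisible(x)
}

#' Export a network graph as a compressed edge list
#'
#' Writes a gzip-compressed CSV with columns `source_class`, `pre`,
#' `post`, preceded by commented header lines carrying the graph
#' dimensions so the file round-trips through [read_edge_list()].
#'
#' @param graph a `network_graph`.
#' @param path output path (a `.csv.gz` file).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "network_graph"))
  con <- gzfile(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("# n_rs=%d n_fs=%d n_ext=%d p=%g p_ext=%g delay=%g seed=%d",
                     graph$n_rs, graph$n_fs, graph$n_ext, graph$p,
                     graph$p_ext, graph$delay, graph$seed), con)
  writeLines("source_class,pre,post", con)
  for (class in c("rs", "fs", "ext", "stim")) {
    adj <- graph[[class]]
    if (!length(adj$tgt)) next
    pre <- rep.int(seq_len(length(adj$ptr) - 1L), diff(adj$ptr))
    writeLines(paste(toupper(class), pre, adj$tgt, sep = ","), con)
  }
  invisible(path)
}

#' Import a network graph written by [write_edge_list()]
#'
#' @param path a `.csv.gz` file produced by [write_edge_list()].
#' @return A `network_graph`.
#' @export
read_edge_list <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  header <- readLines(con, n = 1L)
  meta <- regmatches(header, gregexpr("[a-z_]+=[-0-9.e]+", header))[[1]]
  vals <- stats::setNames(as.numeric(sub(".*=", "", meta)),
                          sub("=.*", "", meta))
  df <- utils::read.csv(con)
  build_csr <- function(class, n_pre) {
    sub <- df[df$source_class == class, , drop = FALSE]
    sub <- sub[order(sub$pre), , drop = FALSE]
    ptr <- integer(n_pre + 1L)
    counts <- tabulate(sub$pre, nbins = n_pre)
    ptr[-1L] <- cumsum(counts)
    list(ptr = ptr, tgt = as.integer(sub$post))
  }
  structure(list(rs = build_csr("RS", vals[["n_rs"]]),
                 fs = build_csr("FS", vals[["n_fs"]]),
                 ext = build_csr("EXT", vals[["n_ext"]]),
                 stim = build_csr("STIM", vals[["n_ext"]]),
                 n_rs = as.integer(vals[["n_rs"]]),
                 n_fs = as.integer(vals[["n_fs"]]),
                 n_ext = as.integer(vals[["n_ext"]]),
                 p = vals[["p"]], p_ext = vals[["p_ext"]],
                 delay = vals[["delay"]], seed = as.integer(vals[["seed"]])),
            class = "network_graph")
}
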