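#' Spatial layout of the recorded subset and electrode
#'
#' The LFP proxy is computed from a subset of neurons given positions in
#' a 2D plane (the layer of the somata), with the electrode at the centre
#' of the layout. By default 50 neurons are placed uniformly at random in
#' a square, sampled proportionally from the two classes (40 RS / 10 FS
#' for the default class sizes).
#'
#' @param graph a [build_graph()] network (supplies class sizes).
#' @param n_neurons subset size.
#' @param side side length of the square layout (micrometres).
#' @param seed integer seed for neuron choice and placement.
#'
#' @return An object of class `spatial_layout`: tibble-backed positions
#'   plus the electrode coordinates.
#' @export
spatial_layout <- function(graph, n_neurons = 50, side = 400, seed = 1L) {
  stopifnot(inherits(graph, "network_graph"))
  n <- graph$n_rs + graph$n_fs
  n_neurons <- min(n_neurons, n)
  n_rs_pick <- round(n_neurons * graph$n_rs / n)
  n_fs_pick <- n_neurons - n_rs_pick
  lay <- with_local_seed(derive_seed(seed, "layout"), {
    ids <- c(sample.int(graph$n_rs, n_rs_pick),
             graph$n_rs + sample.int(graph$n_fs, n_fs_pick))
    tibble::tibble(neuron = ids,
                   class = factor(ifelse(ids <= graph$n_rs, "RS", "FS"),
                                  levels = c("RS", "FS")),
                   x = stats::runif(n_neurons, 0, side),
                   y = stats::runif(n_neurons, 0, side))
  })
  structure(list(positions = lay,
                 electrode = c(x = side / 2, y = side / 2),
                 side = side, seed = as.integer(seed)),
            class = "spatial_layout")
}

#' Unitary-LFP kernel parameters
#'
#' Parameters of the distance- and type-dependent unitary LFP (uLFP)
#' waveform: the field contributed by a single neuron's spike, modelled
#' as a Gaussian in time whose amplitude decays exponentially with
#' distance from the electrode and whose peak is delayed by a constant
#' offset plus axonal conduction time. Inhibitory uLFPs are larger than
#' excitatory ones and of opposite sign at the soma layer, so population
#' LFPs are dominated by inhibition. Absolute amplitudes only scale the
#' LFP; all spectral analyses in the package are amplitude-invariant.
#'
#' @param a0_exc,a0_inh peak uLFP amplitude at zero distance (microvolts)
#'   for excitatory and inhibitory source neurons.
#' @param lambda amplitude space constant (micrometres).
#' @param sigma_t temporal Gaussian SD (ms).
#' @param v_axon axonal conduction speed (micrometres/ms).
#' @param d0 constant peak delay (ms).
#' @param fs LFP sampling rate (Hz).
#'
#' @return An object of class `kernel_params`.
#' @export
kernel_params <- function(a0_exc = 0.15, a0_inh = -0.3, lambda = 200,
                          sigma_t = 2.1, v_axon = 200, d0 = 10.4,
                          fs = 1000) {
  stopifnot_scalar(lambda, "lambda", positive = TRUE)
  stopifnot_scalar(sigma_t, "sigma_t", positive = TRUE)
  stopifnot_scalar(v_axon, "v_axon", positive = TRUE)
  stopifnot_scalar(fs, "fs", positive = TRUE)
  structure(list(a0_exc = a0_exc, a0_inh = a0_inh, lambda = lambda,
                 sigma_t = sigma_t, v_axon = v_axon, d0 = d0, fs = fs),
            class = "kernel_params")
}

#' Evaluate a unitary-LFP kernel
#'
#' Returns the uLFP waveform of one neuron at a given distance from the
#' electrode: amplitude `A0 * exp(-distance / lambda)` (A0 by cell
#' class), Gaussian in time with SD `sigma_t`, peaking at
#' `d0 + distance / v_axon` after the spike.
#'
#' @param t time after the spike (ms); vectorized.
#' @param distance electrode distance (micrometres).
#' @param cell_class `"RS"` (excitatory) or `"FS"` (inhibitory).
#' @param params a [kernel_params()].
#'
#' @return Kernel values (microvolts) at `t`.
#' @export
ulfp_kernel <- function(t, distance, cell_class = c("RS", "FS"),
                        params = kernel_params()) {
  cell_class <- match.arg(cell_class)
  stopifnot_scalar(distance, "distance", nonneg = TRUE)
  a0 <- if (cell_class == "RS") params$a0_exc else params$a0_inh
  amp <- a0 * exp(-distance / params$lambda)
  centre <- params$d0 + distance / params$v_axon
  amp * exp(-(t - centre)^2 / (2 * params$sigma_t^2))
}

#' Kernel-based LFP proxy from network spikes
#'
#' Computes the LFP seen by the electrode as the sum, over every spike of
#' the laid-out neurons, of that neuron's distance- and type-dependent
#' uLFP kernel. The result is linear and time-invariant in the spike
#' trains. Internally each neuron's spike train is binned at the LFP
#' sampling rate and convolved with its kernel.
#'
#' @param sim a `gamma_sim` (or anything with a `spikes` tibble and
#'   `meta$duration`).
#' @param layout a [spatial_layout()].
#' @param params a [kernel_params()].
#' @param from,to time span of the output trace (ms); default full run.
#'
#' @return An object of class `lfp_trace`: tibble with `time` (ms) and
#'   `lfp` (microvolts), sampled at `params$fs`.
#' @export
compute_lfp <- function(sim, layout, params = kernel_params(),
                        from = 0, to = NULL) {
  stopifnot(inherits(layout, "spatial_layout"),
            inherits(params, "kernel_params"))
  if (is.null(to)) to <- sim$meta$duration
  dt_lfp <- 1000 / params$fs
  n_out <- as.integer(floor((to - from) / dt_lfp))
  t_out <- from + seq_len(n_out) * dt_lfp
  lfp <- numeric(n_out)
  pos <- layout$positions
  if (nrow(pos) == 0) {
    warning("empty layout subset: returning an all-zero LFP trace")
  }
  spikes <- sim$spikes
  for (j in seq_len(nrow(pos))) {
    id <- pos$neuron[j]
    st <- spikes$time[spikes$neuron == id]
    if (!length(st)) next
    d <- sqrt((pos$x[j] - layout$electrode[["x"]])^2 +
                (pos$y[j] - layout$electrode[["y"]])^2)
    centre <- params$d0 + d / params$v_axon
    half_width <- 4 * params$sigma_t
    k_lo <- floor((centre - half_width) / dt_lfp)
    k_hi <- ceiling((centre + half_width) / dt_lfp)
    k_off <- k_lo:k_hi
    a0 <- if (pos$class[j] == "RS") params$a0_exc else params$a0_inh
    amp <- a0 * exp(-d / params$lambda)
    for (ts in st) {
      # sample index of the spike on the output grid (time t_out[i] = bin i)
      base <- (ts - from) / dt_lfp
      idx <- floor(base) + k_off
      keep <- idx >= 1 & idx <= n_out
      if (!any(keep)) next
      tt <- t_out[idx[keep]] - ts
      lfp[idx[keep]] <- lfp[idx[keep]] +
        amp * exp(-(tt - centre)^2 / (2 * params$sigma_t^2))
    }
  }
  structure(tibble::tibble(time = t_out, lfp = lfp),
            fs = params$fs, class = c("lfp_trace", class(tibble::tibble())))
}

#' Write an LFP trace as CSV
#'
#' @param trace an `lfp_trace`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lfp <- function(trace, path) {
  utils::write.csv(data.frame(t_ms = trace$time, lfp_uV = trace$lfp),
                   path, row.names = FALSE)
  invisible(path)
}
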