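#' Simulation configuration
#'
#' Bundles the numerical settings, cell and synapse parameters, and the
#' NMDA condition of one network simulation. The condition is the pair of
#' NMDA quantal strengths onto RS and FS cells; lowering them (more
#' strongly on FS) emulates increasing NMDA-receptor antagonist dose.
#'
#' @param dt integration step (ms); forward Euler.
#' @param duration total simulated time (ms), a multiple of `dt`.
#' @param transient initial stretch (ms) discarded by the analysis
#'   functions as settling time.
#' @param condition numeric pair `c(q_nmda_rs, q_nmda_fs)` (nS).
#' @param rs,fs [neuron_params()] for the two classes.
#' @param syn a [synapse_params()]; its `q_nmda_*` entries are overridden
#'   by `condition`.
#' @param v_cut spike detection potential (mV); `NULL` uses each class's
#'   `V_th` (the exponential term then never exceeds `g_L * Delta` at
#'   detection).
#' @param mean_v_every interval between population mean-potential samples
#'   (ms).
#' @param nmda_sum_every interval (ms) at which the per-neuron NMDA
#'   gating sums over presynaptic sources are refreshed. The gating
#'   itself advances every step; only the summation over in-neighbours
#'   is decimated. The default recomputes every step (`dt`); the scale
#'   profiles use 0.5 ms, far below the 2 ms NMDA rise time.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.1, duration = 2000, transient = 500,
                       condition = c(0.8, 1.0),
                       rs = rs_params(), fs = fs_params(),
                       syn = synapse_params(), v_cut = NULL,
                       mean_v_every = 1, nmda_sum_every = NULL) {
  stopifnot_scalar(dt, "dt", positive = TRUE)
  stopifnot_scalar(duration, "duration", positive = TRUE)
  n_steps <- round(duration / dt)
  if (abs(n_steps * dt - duration) > 1e-9) {
    stop("`duration` must be a multiple of `dt`", call. = FALSE)
  }
  stopifnot(length(condition) == 2, all(condition >= 0))
  syn$q_nmda_rs <- condition[[1]]
  syn$q_nmda_fs <- condition[[2]]
  structure(list(dt = dt, duration = duration, transient = transient,
                 condition = c(q_nmda_rs = condition[[1]],
                               q_nmda_fs = condition[[2]]),
                 rs = rs, fs = fs, syn = syn, v_cut = v_cut,
                 mean_v_every = mean_v_every,
                 nmda_sum_every = if (is.null(nmda_sum_every)) dt else
                   nmda_sum_every),
            class = "sim_config")
}

#' Run one network simulation
#'
#' Integrates the full network with forward Euler at `config$dt`. Within
#' each step the update order is fixed: delayed spikes are delivered,
#' conductances and NMDA gating advance, synaptic currents are evaluated
#' at the pre-step voltage, the membrane and adaptation equations take an
#' Euler step, and threshold crossings are detected and reset (with entry
#' into the refractory clamp at `V_rest`). Spike times are recorded at the
#' step of detection. The run is a pure function of the graph, config and
#' the seeds inside `drive` and `stimulus`.
#'
#' @param graph a [build_graph()] network.
#' @param config a [sim_config()].
#' @param drive a [drive_spec()] background drive (AMPA only).
#' @param stimulus optional [stimulus_spec()] (AMPA + NMDA).
#' @param record_ids neuron ids whose state (V, w, conductances, gating,
#'   currents, excitatory arrival markers) is recorded at full `dt`
#'   resolution.
#' @param init_v initial membrane potentials: `"rest"` starts every
#'   neuron at `E_L`; `"random"` draws each neuron uniformly between its
#'   `E_L` and `V_th` (seeded from the graph and drive seeds, so paired
#'   runs share the same draw). The active gamma/AI regime of this
#'   network is self-sustained and lies well above the drive-only
#'   resting state, so the randomized start is used by the experiment
#'   drivers to ignite it inside the discarded transient.
#' @param v0,w0 optional initial state vectors (length `n_rs + n_fs`);
#'   `v0` overrides `init_v`.
#' @param i_inject optional per-neuron constant injected current (pA,
#'   depolarizing positive).
#' @param forced_spikes optional data frame with columns `neuron` and
#'   `time` (ms): those neurons are made to spike at the step containing
#'   `time` (unless refractory), regardless of voltage.
#'
#' @return An object of class `gamma_sim`: list with `spikes` (tibble
#'   `neuron`, `class`, `time`), `mean_v` (tibble `time`, `rs`, `fs`),
#'   `traces` (recorded state, or `NULL`) and `meta`.
#' @export
run_network <- function(graph, config = sim_config(), drive = drive_spec(),
                        stimulus = NULL, record_ids = integer(0),
                        init_v = c("rest", "random"),
                        v0 = NULL, w0 = NULL, i_inject = NULL,
                        forced_spikes = NULL) {
  init_v <- match.arg(init_v)
  stopifnot(inherits(graph, "network_graph"), inherits(config, "sim_config"))
  dt <- config$dt
  n_steps <- as.integer(round(config$duration / dt))
  delay_steps <- as.integer(round(graph$delay / dt))
  if (abs(delay_steps * dt - graph$delay) > 1e-9) {
    stop("the synaptic delay must be a multiple of `dt`", call. = FALSE)
  }
  n <- graph$n_rs + graph$n_fs

  dur_drive <- if (is.null(drive$duration)) config$duration else drive$duration
  bg <- sample_poisson_trains(graph$n_ext, drive$mu_ext,
                              min(dur_drive, config$duration), dt,
                              seed = drive$seed)

  q_ext_nmda_rs <- 0
  q_ext_nmda_fs <- 0
  q_ext_ampa_stim <- 0
  if (!is.null(stimulus)) {
    stopifnot(inherits(stimulus, "stimulus_spec"))
    st <- sample_poisson_trains(graph$n_ext,
                                function(t) gaussian_rate(t, stimulus),
                                config$duration, dt, seed = stimulus$seed)
    q_ext_nmda_rs <- if (is.null(stimulus$q_ext_nmda_rs))
      config$condition[["q_nmda_rs"]] else stimulus$q_ext_nmda_rs
    q_ext_nmda_fs <- if (is.null(stimulus$q_ext_nmda_fs))
      config$condition[["q_nmda_fs"]] else stimulus$q_ext_nmda_fs
    q_ext_ampa_stim <- stimulus$q_ext_ampa
  } else {
    st <- list(step = integer(0), train = integer(0))
  }

  if (!is.null(forced_spikes)) {
    fstep <- as.integer(pmax(round(forced_spikes$time / dt) - 1L, 0L))
    ford <- order(fstep)
    forced_id <- as.integer(forced_spikes$neuron)[ford]
    forced_step <- fstep[ford]
  } else {
    forced_id <- integer(0)
    forced_step <- integer(0)
  }

  if (is.null(v0) && init_v == "random") {
    v0 <- with_local_seed(derive_seed(graph$seed, drive$seed, "v0"), {
      c(stats::runif(graph$n_rs, config$rs$E_L, config$rs$V_th),
        stats::runif(graph$n_fs, config$fs$E_L, config$fs$V_th))
    })
  }

  v_cut_rs <- if (is.null(config$v_cut)) NA_real_ else config$v_cut
  v_cut_fs <- v_cut_rs

  res <- .simulate_network_cpp(
    graph$n_rs, graph$n_fs, config$rs, config$fs, config$syn,
    graph$rs$ptr, graph$rs$tgt, graph$fs$ptr, graph$fs$tgt,
    graph$ext$ptr, graph$ext$tgt, graph$stim$ptr, graph$stim$tgt,
    as.integer(bg$step), as.integer(bg$train),
    as.integer(st$step), as.integer(st$train),
    drive$q_ext_ampa, q_ext_ampa_stim, q_ext_nmda_rs, q_ext_nmda_fs,
    dt, n_steps, delay_steps, v_cut_rs, v_cut_fs,
    as.integer(record_ids),
    if (is.null(v0)) numeric(0) else as.numeric(v0),
    if (is.null(w0)) numeric(0) else as.numeric(w0),
    if (is.null(i_inject)) numeric(0) else as.numeric(i_inject),
    forced_id, forced_step,
    as.integer(round(config$mean_v_every / dt)),
    as.integer(max(1, round(config$nmda_sum_every / dt))))

  spikes <- tibble::tibble(
    neuron = res$spike_id,
    class = factor(ifelse(res$spike_id <= graph$n_rs, "RS", "FS"),
                   levels = c("RS", "FS")),
    time = (res$spike_step + 1) * dt)
  traces <- res$traces
  if (!is.null(traces)) traces$time <- seq_len(n_steps) * dt

  structure(list(
    spikes = spikes,
    mean_v = tibble::tibble(time = res$mean_v_time, rs = res$mean_v_rs,
                            fs = res$mean_v_fs),
    traces = traces,
    meta = list(n_rs = graph$n_rs, n_fs = graph$n_fs,
                graph_seed = graph$seed, drive_seed = drive$seed,
                mu_ext = if (is.function(drive$mu_ext)) NA_real_ else
                  drive$mu_ext,
                stimulus = if (is.null(stimulus)) NULL else
                  stimulus[c("amplitude", "sigma", "center", "seed")],
                condition = config$condition, dt = dt,
                duration = config$duration, transient = config$transient)),
    class = "gamma_sim")
}

#' @export
print.gamma_sim <- function(x, ...) {
  m <- x$meta
  cat(sprintf("Network simulation: %d RS + %d FS, %g ms at dt = %g ms\n",
              m$n_rs, m$n_fs, m$duration, m$dt))
  cat(sprintf("  condition Q_NMDA = (%g, %g) nS, drive %g Hz, %d spikes\n",
              m$condition[["q_nmda_rs"]], m$condition[["q_nmda_fs"]],
              m$mu_ext, nrow(x$spikes)))
  invisible(x)
}

#' Paired stimulus / no-stimulus simulation
#'
#' Runs the network twice with the identical connectivity and the
#' identical background-drive realization (common random numbers): once
#' with the Gaussian stimulus and once without it. Because the stimulus
#' spikes come from an independent seed stream, the two runs differ only
#' by the stimulus, so spike-count differences isolate its effect; with
#' `amplitude = 0` the two runs are identical.
#'
#' @inheritParams run_network
#' @param stimulus a [stimulus_spec()] (required).
#'
#' @return An object of class `paired_sim`: list with elements `with` and
#'   `without`, both `gamma_sim`.
#' @export
#' @param init_v initial-potential mode, passed to [run_network()] for
#'   both members of the pair (they share the same draw).
paired_run <- function(graph, config = sim_config(), drive = drive_spec(),
                       stimulus = stimulus_spec(1),
                       init_v = c("rest", "random")) {
  stopifnot(inherits(stimulus, "stimulus_spec"))
  init_v <- match.arg(init_v)
  with_stim <- run_network(graph, config, drive, stimulus, init_v = init_v)
  without <- run_network(graph, config, drive, stimulus = NULL,
                         init_v = init_v)
  structure(list(with = with_stim, without = without), class = "paired_sim")
}

#' Population firing rates of a simulation
#'
#' @param sim a `gamma_sim`.
#' @param from start of the counting window (ms); defaults to the
#'   configured transient.
#' @param to end of the counting window (ms); defaults to the duration.
#' @return Named numeric `c(rs = Hz, fs = Hz)` per-neuron mean rates.
#' @export
firing_rates <- function(sim, from = NULL, to = NULL) {
  stopifnot(inherits(sim, "gamma_sim"))
  if (is.null(from)) from <- sim$meta$transient
  if (is.null(to)) to <- sim$meta$duration
  sp <- sim$spikes[sim$spikes$time > from & sim$spikes$time <= to, ]
  span_s <- (to - from) / 1000
  c(rs = sum(sp$class == "RS") / (sim$meta$n_rs * span_s),
    fs = sum(sp$class == "FS") / (sim$meta$n_fs * span_s))
}

#' Export spikes as CSV
#'
#' @param sim a `gamma_sim`.
#' @param path output path; `.gz` suffix compresses.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(sim, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  utils::write.csv(data.frame(neuron_id = sim$spikes$neuron,
                              class = as.character(sim$spikes$class),
                              t_ms = sim$spikes$time),
                   con, row.names = FALSE)
  invisible(path)
}
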