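#' Simulation scale profiles
#'
#' Two profiles control the computational scale of the orchestrated
#' experiments. Both use the full-size network (4000 RS + 1000 FS
#' neurons, 5000 external trains): the network's synchrony regime
#' depends on the quantal event size, so shrinking the neuron count
#' while rescaling quanta changes the dynamics qualitatively, and the
#' profiles instead scale the run durations and repeat counts.
#' `"paper"` is the full study (5 s runs; 10 repeats for the weight
#' sweep, 50 for the block trajectory, 15 for responsiveness). `"desk"`
#' uses 2 s runs (1.5 s for responsiveness) and 3-5 repeats, sized for a
#' single workstation CPU, and refreshes the NMDA gating sums every
#' 0.5 ms (see [sim_config()]).
#'
#' @param name `"desk"` or `"paper"`.
#' @return A list of profile settings.
#' @export
sim_profile <- function(name = c("desk", "paper")) {
  name <- match.arg(name)
  if (name == "paper") {
    list(name = "paper", n_rs = 4000L, n_fs = 1000L, n_ext = 5000L,
         reps_sweep = 10L, dur_sweep = 5000,
         reps_traj = 50L, dur_traj = 5000,
         reps_resp = 15L, dur_resp = 2000,
         nmda_sum_every = 0.5)
  } else {
    list(name = "desk", n_rs = 4000L, n_fs = 1000L, n_ext = 5000L,
         reps_sweep = 2L, dur_sweep = 1500,
         reps_traj = 5L, dur_traj = 2000,
         reps_resp = 5L, dur_resp = 1500,
         nmda_sum_every = 0.5)
  }
}

# graph for a profile and replicate seed
profile_graph <- function(profile, seed) {
  build_graph(connectivity_spec(n_rs = profile$n_rs, n_fs = profile$n_fs,
                                n_ext = profile$n_ext, seed = seed))
}

profile_config <- function(profile, condition, duration, transient = 500,
                           tau_decay_nmda = 200) {
  syn <- synapse_params(tau_decay_nmda = tau_decay_nmda)
  sim_config(duration = duration, transient = transient,
             condition = condition, syn = syn,
             nmda_sum_every = profile$nmda_sum_every)
}

# Background drive with an ignition ramp: the self-sustained active
# regime lies above the drive-only resting state, so the drive starts
# slightly elevated and decays to the working rate well inside the
# discarded transient. The ramp is part of the seeded background
# realization, hence identical across paired runs.
profile_drive <- function(profile, mu_ext, seed) {
  drive_spec(mu_ext = function(t) mu_ext + max(0, 3.5 - mu_ext) *
               exp(-t / 150),
             q_ext_ampa = 0.8, seed = seed)
}

#' NMDA-antagonist trajectory in the weight plane
#'
#' Piecewise-linear path in the (Q_NMDA_RS, Q_NMDA_FS) plane from the
#' healthy condition to a strongly blocked one. The FS weight falls
#' faster than the RS weight, encoding the higher antagonist affinity
#' for receptors on inhibitory interneurons.
#'
#' @param n_points number of points including both endpoints.
#' @param from healthy endpoint `c(q_rs, q_fs)` (nS).
#' @param to blocked endpoint `c(q_rs, q_fs)` (nS).
#'
#' @return A tibble with columns `point`, `q_rs`, `q_fs`, class
#'   `trajectory_spec`.
#' @export
nmda_trajectory <- function(n_points = 5, from = c(0.8, 1.0),
                            to = c(0.213, 0.2)) {
  stopifnot(n_points >= 2)
  f <- seq(0, 1, length.out = n_points)
  out <- tibble::tibble(point = seq_len(n_points),
                        q_rs = from[1] + f * (to[1] - from[1]),
                        q_fs = from[2] + f * (to[2] - from[2]))
  class(out) <- c("trajectory_spec", class(out))
  out
}

# one simulation + LFP spectral summary, shared by the experiment drivers
run_point <- function(graph, config, drive, layout, normalize_psd = TRUE,
                      peak_band = c(30, 90), gamma_band = c(30, 90)) {
  sim <- run_network(graph, config, drive, init_v = "random")
  lfp <- compute_lfp(sim, layout, from = config$transient)
  psd <- welch_psd(lfp, normalize = normalize_psd)
  pk <- psd_peak(psd, peak_band)
  state <- classify_state(psd, gamma_band = gamma_band)
  mv <- mean_potentials(sim)
  rates <- firing_rates(sim)
  list(sim = sim, psd = psd,
       row = tibble::tibble(rs_rate = rates[["rs"]], fs_rate = rates[["fs"]],
                            peak_freq = pk$freq, peak_power = pk$power,
                            state = state$label,
                            mean_v_rs = mv$mean_v[1], mean_v_fs = mv$mean_v[2]))
}

#' Sweep the NMDA quantal strengths
#'
#' Simulates the network over a grid of (Q_NMDA_RS, Q_NMDA_FS) values
#' and reports, per grid point, the repeat-averaged RS and FS firing
#' rates and the LFP PSD peak frequency and amplitude (the four summary
#' maps of the weight-plane characterization).
#'
#' @param q_rs_values,q_fs_values grid coordinates (nS, nominal
#'   full-size units).
#' @param reps repeats per grid point; `NULL` uses the profile default.
#' @param duration per-run duration (ms); `NULL` uses the profile default.
#' @param profile `"desk"`, `"paper"`, or a profile list with the
#'   fields of [sim_profile()] (custom scales).
#' @param mu_ext background drive rate (Hz).
#' @param seed master seed; replicate graphs/drives derive from it.
#'
#' @return A tibble with one row per grid point: `q_rs`, `q_fs`,
#'   `rs_rate`, `fs_rate`, `peak_freq`, `peak_power`, `n_reps`.
#' @export
sweep_qnmda <- function(q_rs_values = seq(0, 1, by = 0.05),
                        q_fs_values = seq(0, 1, by = 0.05),
                        reps = NULL, duration = NULL, profile = "desk",
                        mu_ext = 3, seed = 1L) {
  prof <- if (is.list(profile)) profile else sim_profile(profile)
  if (is.null(reps)) reps <- prof$reps_sweep
  if (is.null(duration)) duration <- prof$dur_sweep
  grid <- expand.grid(q_rs = q_rs_values, q_fs = q_fs_values,
                      KEEP.OUT.ATTRS = FALSE)
  reps_idx <- seq_len(reps)
  graphs <- lapply(reps_idx, function(r)
    profile_graph(prof, derive_seed(seed, "sweep-graph", r)))
  layouts <- lapply(reps_idx, function(r)
    spatial_layout(graphs[[r]], seed = derive_seed(seed, "sweep-layout", r)))
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    per_rep <- lapply(reps_idx, function(r) {
      config <- profile_config(prof, c(grid$q_rs[g], grid$q_fs[g]), duration)
      drive <- profile_drive(prof, mu_ext, derive_seed(seed, "sweep-drive", r))
      run_point(graphs[[r]], config, drive, layouts[[r]])$row
    })
    agg <- do.call(rbind, per_rep)
    tibble::tibble(q_rs = grid$q_rs[g], q_fs = grid$q_fs[g],
                   rs_rate = mean(agg$rs_rate), fs_rate = mean(agg$fs_rate),
                   peak_freq = mean(agg$peak_freq),
                   peak_power = mean(agg$peak_power), n_reps = reps)
  })
  do.call(rbind, rows)
}

#' Simulate the NMDA-block trajectory
#'
#' Runs repeat simulations at each point of a [nmda_trajectory()] and
#' collects the repeat-level firing rates, normalized-PSD peak frequency
#' and amplitude, gamma/AI state label, and population mean membrane
#' potentials. Replicate graphs and drive realizations are shared across
#' trajectory points so that within-replicate comparisons along the
#' trajectory are paired.
#'
#' @param traj a [nmda_trajectory()].
#' @param reps repeats per point; `NULL` uses the profile default.
#' @param duration per-run duration (ms); `NULL` uses the profile default.
#' @param profile `"desk"` or `"paper"`.
#' @param mu_ext background drive rate (Hz); 3 Hz keeps the healthy
#'   network in the gamma regime.
#' @param seed master seed.
#' @param normalize_psd divide each PSD by its total power before peak
#'   extraction and averaging.
#'
#' @return A tibble with one row per (point, rep): trajectory
#'   coordinates plus the per-run summaries. Attribute `psd` holds the
#'   across-repeat average PSD per trajectory point (matrix bins x
#'   points) with `freqs`.
#' @export
trajectory_experiment <- function(traj = nmda_trajectory(), reps = NULL,
                                  duration = NULL, profile = "desk",
                                  mu_ext = 3, seed = 1L,
                                  normalize_psd = TRUE) {
  prof <- if (is.list(profile)) profile else sim_profile(profile)
  if (is.null(reps)) reps <- prof$reps_traj
  if (is.null(duration)) duration <- prof$dur_traj
  reps_idx <- seq_len(reps)
  graphs <- lapply(reps_idx, function(r)
    profile_graph(prof, derive_seed(seed, "traj-graph", r)))
  layouts <- lapply(reps_idx, function(r)
    spatial_layout(graphs[[r]], seed = derive_seed(seed, "traj-layout", r)))
  rows <- list()
  psd_acc <- NULL
  freqs <- NULL
  for (g in seq_len(nrow(traj))) {
    for (r in reps_idx) {
      config <- profile_config(prof, c(traj$q_rs[g], traj$q_fs[g]), duration)
      drive <- profile_drive(prof, mu_ext, derive_seed(seed, "traj-drive", r))
      res <- run_point(graphs[[r]], config, drive, layouts[[r]],
                       normalize_psd = normalize_psd)
      rows[[length(rows) + 1L]] <-
        cbind(tibble::tibble(point = traj$point[g], q_rs = traj$q_rs[g],
                             q_fs = traj$q_fs[g], rep = r), res$row)
      if (is.null(psd_acc)) {
        freqs <- res$psd$freqs
        psd_acc <- matrix(0, length(freqs), nrow(traj))
      }
      psd_acc[, g] <- psd_acc[, g] + res$psd$power / reps
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "psd") <- list(freqs = freqs, power = psd_acc,
                           q_fs = traj$q_fs)
  out
}

#' Responsiveness protocol over stimulus amplitudes
#'
#' For each Gaussian stimulus amplitude, runs paired (stimulus /
#' no-stimulus) simulations sharing the background-drive realization and
#' computes the responsiveness of the RS, FS and whole-network
#' populations inside a window centred on the stimulus. The network
#' state is selected through the background drive rate: 3 Hz for the
#' gamma regime, 2 Hz for the asynchronous-irregular (AI) regime.
#'
#' @param amplitudes stimulus peak amplitudes (Hz per train).
#' @param condition nominal NMDA condition `c(q_rs, q_fs)` (nS).
#' @param state `"gamma"` or `"AI"`.
#' @param reps paired repeats per amplitude; `NULL` for profile default.
#' @param profile `"desk"` or `"paper"`.
#' @param T responsiveness window (ms).
#' @param sigma stimulus envelope SD (ms).
#' @param duration per-run duration (ms); `NULL` for profile default.
#'   The stimulus is centred midway through the post-transient stretch.
#' @param tau_decay_nmda NMDA decay time constant (ms); override to 50
#'   for the fast-NMDA variant.
#' @param seed master seed.
#'
#' @return A tibble with one row per (amplitude, rep): `amplitude`,
#'   `rep`, `r_rs`, `r_fs`, `r_all` (spikes/s/neuron), `state`,
#'   `q_rs`, `q_fs`.
#' @export
responsiveness_protocol <- function(amplitudes = seq(0.5, 2.5, by = 0.5),
                                    condition = c(0.8, 1.0),
                                    state = c("gamma", "AI"), reps = NULL,
                                    profile = "desk", T = 500, sigma = 50,
                                    duration = NULL, tau_decay_nmda = 200,
                                    seed = 1L) {
  state <- match.arg(state)
  prof <- if (is.list(profile)) profile else sim_profile(profile)
  if (is.null(reps)) reps <- prof$reps_resp
  if (is.null(duration)) duration <- prof$dur_resp
  mu_ext <- if (state == "gamma") 3 else 2
  transient <- 500
  center <- transient + (duration - transient) / 2
  if (center - T / 2 < transient) {
    stop("duration too short for the responsiveness window", call. = FALSE)
  }
  reps_idx <- seq_len(reps)
  graphs <- lapply(reps_idx, function(r)
    profile_graph(prof, derive_seed(seed, "resp-graph", r)))
  rows <- list()
  for (a in amplitudes) {
    for (r in reps_idx) {
      config <- profile_config(prof, condition, duration,
                               transient = transient,
                               tau_decay_nmda = tau_decay_nmda)
      drive <- profile_drive(prof, mu_ext, derive_seed(seed, "resp-drive", r))
      stim <- stimulus_spec(amplitude = a, sigma = sigma, center = center,
                            q_ext_ampa = 0.8,
                            seed = derive_seed(seed, "resp-stim", r))
      pair <- paired_run(graphs[[r]], config, drive, stim,
                         init_v = "random")
      rows[[length(rows) + 1L]] <- tibble::tibble(
        amplitude = a, rep = r,
        r_rs = responsiveness(pair, "RS", T = T)$R,
        r_fs = responsiveness(pair, "FS", T = T)$R,
        r_all = responsiveness(pair, "all", T = T)$R,
        state = state, q_rs = condition[1], q_fs = condition[2])
    }
  }
  do.call(rbind, rows)
}

#' Responsiveness protocol with fast NMDA kinetics
#'
#' Same protocol as [responsiveness_protocol()] but with the NMDA decay
#' time constant shortened to 50 ms (rise unchanged at 2 ms) and a
#' coarser default amplitude grid.
#'
#' @inheritParams responsiveness_protocol
#' @return See [responsiveness_protocol()].
#' @export
fast_nmda_variant <- function(amplitudes = seq(0.25, 2.5, by = 0.25),
                              condition = c(0.8, 1.0),
                              state = c("gamma", "AI"), reps = NULL,
                              profile = "desk", T = 500, sigma = 50,
                              duration = NULL, seed = 1L) {
  responsiveness_protocol(amplitudes = amplitudes, condition = condition,
                          state = state, reps = reps, profile = profile,
                          T = T, sigma = sigma, duration = duration,
                          tau_decay_nmda = 50, seed = seed)
}
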