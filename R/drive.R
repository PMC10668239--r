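#' Background external drive specification
#'
#' The network is kept active by a pool of independent, identically
#' distributed Poisson spike trains wired to the neurons with the
#' probability of [connectivity_spec()]. The drive feeds the AMPA
#' conductance only. A rate of 3 Hz per train puts the default network in
#' the gamma-oscillatory regime; 2 Hz yields the asynchronous-irregular
#' (AI) regime.
#'
#' @param mu_ext background rate per train (Hz): a scalar, or a function
#'   of time `mu_ext(t_ms)` -> Hz (useful for ignition ramps that settle
#'   onto the working rate inside the discarded transient).
#' @param q_ext_ampa quantal AMPA conductance of drive synapses (nS).
#' @param duration optional drive duration (ms); defaults to the
#'   simulation duration when `NULL`.
#' @param seed integer seed of the drive realization.
#'
#' @return An object of class `drive_spec`.
#' @export
drive_spec <- function(mu_ext = 3, q_ext_ampa = 0.8, duration = NULL,
                       seed = 1L) {
  if (!is.function(mu_ext)) stopifnot_scalar(mu_ext, "mu_ext", nonneg = TRUE)
  stopifnot_scalar(q_ext_ampa, "q_ext_ampa", nonneg = TRUE)
  structure(list(mu_ext = mu_ext, q_ext_ampa = q_ext_ampa,
                 duration = duration, seed = as.integer(seed)),
            class = "drive_spec")
}

#' Gaussian-envelope stimulus specification
#'
#' A transient stimulus delivered through a second pool of Poisson
#' trains whose rate follows a Gaussian envelope in time,
#' `amplitude * exp(-(t - center)^2 / (2 sigma^2))`. The default SD of
#' 50 ms makes the stimulus slow relative to the gamma cycle (it spans
#' roughly three 60-Hz cycles). Stimulus spikes feed both the AMPA and
#' the NMDA external conductances; the background drive feeds AMPA only.
#'
#' @param amplitude peak rate increase per train (Hz).
#' @param sigma envelope SD (ms).
#' @param center envelope peak time (ms).
#' @param q_ext_ampa quantal AMPA conductance of stimulus synapses (nS).
#' @param q_ext_nmda_rs,q_ext_nmda_fs quantal NMDA conductances of
#'   stimulus synapses onto RS and FS cells (nS); `NULL` means "inherit
#'   the recurrent NMDA strengths of the simulated condition".
#' @param seed integer seed of the stimulus realization.
#'
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(amplitude, sigma = 50, center = 1000,
                          q_ext_ampa = 0.8,
                          q_ext_nmda_rs = NULL, q_ext_nmda_fs = NULL,
                          seed = 1L) {
  stopifnot_scalar(amplitude, "amplitude", nonneg = TRUE)
  stopifnot_scalar(sigma, "sigma", positive = TRUE)
  stopifnot_scalar(center, "center")
  structure(list(amplitude = amplitude, sigma = sigma, center = center,
                 q_ext_ampa = q_ext_ampa,
                 q_ext_nmda_rs = q_ext_nmda_rs,
                 q_ext_nmda_fs = q_ext_nmda_fs,
                 seed = as.integer(seed)),
            class = "stimulus_spec")
}

#' Stimulus rate envelope
#'
#' @param t time (ms); vectorized.
#' @param spec a [stimulus_spec()].
#' @return Rate increase at `t` (Hz per train).
#' @export
gaussian_rate <- function(t, spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  spec$amplitude * exp(-(t - spec$center)^2 / (2 * spec$sigma^2))
}

#' Sample a pool of (in)homogeneous Poisson spike trains
#'
#' Spikes are drawn per train and per time step as independent Bernoulli
#' events with probability `rate(t) * dt` (rate converted to 1/ms), the
#' same discretization the simulation engine uses, so sampled trains can
#' be fed to the engine without regridding. Inhomogeneous rates are
#' sampled exactly by thinning a homogeneous Bernoulli process at the
#' peak rate.
#'
#' @param n_trains number of independent trains.
#' @param rate scalar rate (Hz) or a function of time `rate(t_ms)` -> Hz.
#' @param duration total duration (ms).
#' @param dt time step (ms).
#' @param seed integer seed.
#'
#' @return A tibble with columns `train` (1-based id), `step` (0-based
#'   time-step index) and `time` (ms, the end of the step), sorted by
#'   `step`. Attribute `n_trains` carries the pool size.
#' @export
sample_poisson_trains <- function(n_trains, rate, duration, dt = 0.1,
                                  seed = 1L) {
  stopifnot_scalar(n_trains, "n_trains", nonneg = TRUE)
  stopifnot_scalar(duration, "duration", positive = TRUE)
  stopifnot_scalar(dt, "dt", positive = TRUE)
  n_steps <- as.integer(round(duration / dt))
  t_grid <- (seq_len(n_steps) - 1L) * dt
  rate_fn_given <- is.function(rate)
  rates <- if (rate_fn_given) rate(t_grid) else rep(rate, n_steps)
  if (any(rates < 0)) stop("negative rate", call. = FALSE)
  p_step <- rates / 1000 * dt
  p_max <- max(p_step)
  if (p_max > 0.1) {
    warning("rate * dt exceeds 0.1 somewhere: the Bernoulli approximation of the Poisson process is degraded")
  }
  out <- with_local_seed(derive_seed(seed, "poisson-trains"), {
    if (p_max == 0 || n_trains == 0) {
      list(train = integer(0), step = integer(0))
    } else {
      # candidate events at the peak rate, then thin to the local rate
      counts <- stats::rbinom(n_trains, n_steps, p_max)
      train <- rep.int(seq_len(n_trains), counts)
      step <- unlist(lapply(counts, function(k) {
        if (k == 0L) integer(0) else sample.int(n_steps, k) - 1L
      }), use.names = FALSE)
      if (p_max < 1 && length(step)) {
        keep <- stats::runif(length(step)) < p_step[step + 1L] / p_max
        train <- train[keep]
        step <- step[keep]
      }
      list(train = train, step = step)
    }
  })
  ord <- order(out$step, out$train)
  res <- tibble::tibble(train = out$train[ord], step = out$step[ord],
                        time = (out$step[ord] + 1L) * dt)
  attr(res, "n_trains") <- as.integer(n_trains)
  attr(res, "dt") <- dt
  res
}

#' Write spike trains as a two-column text file
#'
#' @param trains a [sample_poisson_trains()] result.
#' @param path output file (CSV: `train`, `time_ms`).
#' @return `path`, invisibly.
#' @export
write_trains <- function(trains, path) {
  utils::write.csv(data.frame(train = trains$train, time_ms = trains$time),
                   path, row.names = FALSE)
  invisible(path)
}
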