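#' Welch power spectral density
#'
#' Welch's method with a periodic Hamming window of `window_sec` seconds
#' (250 samples at the default 1 kHz) and a fixed segment overlap of
#' `overlap` samples (125, i.e. 50% at the defaults, giving a 4 Hz
#' frequency resolution). Each segment is mean-detrended and windowed;
#' one-sided modified periodograms are averaged and scaled to power
#' density (signal units squared per Hz), matching the conventional
#' Welch estimator.
#'
#' @param x the signal: numeric vector, or an `lfp_trace` (its sampling
#'   rate is then taken from the trace).
#' @param fs sampling rate (Hz).
#' @param window_sec window length (s).
#' @param overlap segment overlap (samples).
#' @param normalize if `TRUE`, divide the PSD by its total power so
#'   spectra of different runs are comparable in shape.
#'
#' @return An object of class `psd_result`: list with `freqs` (Hz),
#'   `power`, `peak_freq` and `peak_power` (peak over positive
#'   frequencies), `fs`, `normalized`.
#' @export
welch_psd <- function(x, fs = 1000, window_sec = 0.25, overlap = 125,
                      normalize = FALSE) {
  if (inherits(x, "lfp_trace")) {
    fs <- attr(x, "fs")
    x <- x$lfp
  }
  x <- as.numeric(x)
  nper <- as.integer(round(window_sec * fs))
  if (length(x) < nper) {
    stop(sprintf("signal too short for Welch PSD: need at least %d samples (%g s at %g Hz), got %d",
                 nper, window_sec, fs, length(x)), call. = FALSE)
  }
  overlap <- as.integer(overlap)
  if (overlap >= nper) stop("`overlap` must be smaller than the window",
                            call. = FALSE)
  step <- nper - overlap
  n_seg <- (length(x) - nper) %/% step + 1L
  # periodic Hamming window
  win <- 0.54 - 0.46 * cos(2 * pi * (0:(nper - 1)) / nper)
  scale <- 1 / (fs * sum(win^2))
  n_freq <- nper %/% 2L + 1L
  acc <- numeric(n_freq)
  for (k in seq_len(n_seg)) {
    seg <- x[((k - 1L) * step + 1L):((k - 1L) * step + nper)]
    seg <- (seg - mean(seg)) * win
    ft <- stats::fft(seg)[seq_len(n_freq)]
    p <- (Re(ft)^2 + Im(ft)^2) * scale
    # one-sided: double everything except DC and (even nper) Nyquist
    dbl <- rep(2, n_freq)
    dbl[1] <- 1
    if (nper %% 2L == 0L) dbl[n_freq] <- 1
    acc <- acc + p * dbl
  }
  power <- acc / n_seg
  freqs <- (seq_len(n_freq) - 1L) * fs / nper
  if (normalize) {
    tot <- sum(power)
    if (tot > 0) power <- power / tot
  }
  ipk <- which.max(power[-1]) + 1L
  structure(list(freqs = freqs, power = power,
                 peak_freq = freqs[ipk], peak_power = power[ipk],
                 fs = fs, n_segments = n_seg, normalized = normalize),
            class = "psd_result")
}

#' @export
print.psd_result <- function(x, ...) {
  cat(sprintf("Welch PSD: %d bins up to %g Hz (%g Hz resolution, %d segments)\n",
              length(x$freqs), max(x$freqs), x$freqs[2], x$n_segments))
  cat(sprintf("  dominant peak: %g Hz (power %.3g%s)\n", x$peak_freq,
              x$peak_power, if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Peak of a PSD within a frequency band
#'
#' @param psd a [welch_psd()] result.
#' @param band numeric pair `c(lo, hi)` (Hz).
#' @return List with `freq` and `power` of the in-band maximum.
#' @export
psd_peak <- function(psd, band = c(30, 90)) {
  sel <- psd$freqs >= band[1] & psd$freqs <= band[2]
  if (!any(sel)) stop("no frequency bins inside the band", call. = FALSE)
  i <- which(sel)[which.max(psd$power[sel])]
  list(freq = psd$freqs[i], power = psd$power[i])
}

#' Classify a network state as gamma-oscillatory or asynchronous
#'
#' A state counts as gamma when the PSD has a dominant peak in the gamma
#' band: the in-band maximum must exceed `threshold` times the median
#' power over the 20-200 Hz comparison range, excluding the bins within
#' `exclude_hz` of the peak itself. Otherwise the state is labelled AI
#' (asynchronous-irregular). AI states may still show a small gamma bump;
#' the criterion asks that the peak be large relative to the other
#' fluctuations of the spectrum.
#'
#' @param psd a [welch_psd()] result of the LFP.
#' @param gamma_band gamma frequency band (Hz).
#' @param threshold dominance ratio (peak over median baseline).
#' @param compare_band range whose median forms the baseline (Hz).
#' @param exclude_hz half-width of the neighbourhood around the peak
#'   excluded from the baseline (Hz).
#'
#' @return An object of class `state_label`: list with `label`
#'   (`"gamma"` or `"AI"`), `peak_freq`, `peak_power` and
#'   `peak_prominence_ratio`.
#' @export
classify_state <- function(psd, gamma_band = c(30, 90), threshold = 5,
                           compare_band = c(20, 200), exclude_hz = 8) {
  pk <- psd_peak(psd, gamma_band)
  base_sel <- psd$freqs >= compare_band[1] & psd$freqs <= compare_band[2] &
    abs(psd$freqs - pk$freq) > exclude_hz
  baseline <- stats::median(psd$power[base_sel])
  ratio <- if (baseline > 0) pk$power / baseline else Inf
  label <- if (ratio >= threshold) "gamma" else "AI"
  structure(list(label = label, peak_freq = pk$freq,
                 peak_power = pk$power, peak_prominence_ratio = ratio,
                 threshold = threshold, gamma_band = gamma_band),
            class = "state_label")
}

#' @export
print.state_label <- function(x, ...) {
  cat(sprintf("state: %s (peak %g Hz, prominence ratio %.2f, threshold %g)\n",
              x$label, x$peak_freq, x$peak_prominence_ratio, x$threshold))
  invisible(x)
}

#' Network responsiveness to a transient stimulus
#'
#' Responsiveness is the extra spiking caused by a stimulus, from a pair
#' of simulations sharing the same background-drive realization:
#' \deqn{R = \frac{N^S - N}{T \, N_n}}
#' where `N^S` and `N` are the spike counts with and without the
#' stimulus inside a window of duration `T` and `N_n` is the normalizing
#' neuron count. Units: spikes per second per neuron (Hz). When a
#' population (`"RS"` or `"FS"`) is selected, counts and `N_n` are
#' restricted to that population; `"all"` uses the whole network.
#'
#' @param pair a [paired_run()] result (or a list with elements `with`
#'   and `without`).
#' @param population `"all"`, `"RS"` or `"FS"`.
#' @param T window duration (ms).
#' @param center window centre (ms); defaults to the stimulus centre
#'   recorded in the run metadata, so the window spans `center +- T/2`.
#'
#' @return An object of class `responsiveness_result`: list with `R`
#'   (Hz), the raw counts, `population`, `T`, `N_n` and the stimulus
#'   amplitude.
#' @export
responsiveness <- function(pair, population = c("all", "RS", "FS"),
                           T = 500, center = NULL) {
  population <- match.arg(population)
  a <- pair$with
  b <- pair$without
  comparable <- identical(a$meta$graph_seed, b$meta$graph_seed) &&
    identical(a$meta$drive_seed, b$meta$drive_seed) &&
    identical(a$meta$duration, b$meta$duration) &&
    identical(a$meta$dt, b$meta$dt) &&
    identical(a$meta$condition, b$meta$condition)
  if (!comparable) {
    stop("run metadata mismatch: spike counts are not comparable", call. = FALSE)
  }
  if (is.null(center)) {
    if (is.null(a$meta$stimulus)) stop("no stimulus metadata; supply `center`",
                                       call. = FALSE)
    center <- a$meta$stimulus$center
  }
  lo <- center - T / 2
  hi <- center + T / 2
  count <- function(sim) {
    sp <- sim$spikes[sim$spikes$time > lo & sim$spikes$time <= hi, ]
    if (population != "all") sp <- sp[sp$class == population, ]
    nrow(sp)
  }
  n_n <- switch(population, all = a$meta$n_rs + a$meta$n_fs,
                RS = a$meta$n_rs, FS = a$meta$n_fs)
  n_with <- count(a)
  n_without <- count(b)
  structure(list(R = (n_with - n_without) / ((T / 1000) * n_n),
                 n_with = n_with, n_without = n_without,
                 population = population, T = T, N_n = n_n,
                 amplitude = if (is.null(a$meta$stimulus)) NA_real_ else
                   a$meta$stimulus$amplitude,
                 window = c(lo, hi)),
            class = "responsiveness_result")
}

#' @export
print.responsiveness_result <- function(x, ...) {
  cat(sprintf("responsiveness (%s): R = %.4g spikes/s/neuron (%d - %d spikes, T = %g ms, N_n = %d)\n",
              x$population, x$R, x$n_with, x$n_without, x$T, x$N_n))
  invisible(x)
}

#' Synaptic charge over the 10 ms post-input window
#'
#' Trapezoidal area under a synaptic current trace from a presynaptic
#' input time until `window` ms after it. With currents in pA and time in
#' ms the area is returned in pC (1 pA * 1 ms = 1e-3 pC).
#'
#' @param time sample times (ms), regular grid covering the window.
#' @param current synaptic current samples (pA).
#' @param onset presynaptic input time (ms).
#' @param window integration span after the onset (ms).
#'
#' @return Charge (pC), signed as the current.
#' @export
synaptic_charge <- function(time, current, onset, window = 10) {
  sel <- time >= onset & time <= onset + window
  if (!any(sel) || min(time) > onset || max(time) < onset + window) {
    stop("current trace does not cover the full integration window",
         call. = FALSE)
  }
  trapz_integral(time[sel], current[sel]) / 1000
}

#' NMDA/AMPA charge ratios from recorded neurons
#'
#' For each recorded neuron, averages its AMPA and NMDA current snippets
#' aligned on the (delayed) excitatory presynaptic arrival times, takes
#' the charge of each average over the 10 ms post-input window, and
#' forms the NMDA/AMPA ratio of absolute charges. Run the simulation
#' with `record_ids` covering the neurons of interest.
#'
#' @param sim a `gamma_sim` with recorded traces.
#' @param window integration span (ms).
#' @param from earliest onset considered (ms); defaults to the transient.
#'
#' @return A tibble with one row per recorded neuron: `neuron`, `class`,
#'   `n_onsets`, `q_ampa` and `q_nmda` (pC, signed), `ratio`
#'   (|q_nmda| / |q_ampa|).
#' @export
charge_ratios <- function(sim, window = 10, from = NULL) {
  tr <- sim$traces
  if (is.null(tr)) stop("simulation was run without `record_ids`", call. = FALSE)
  if (is.null(from)) from <- sim$meta$transient
  dt <- sim$meta$dt
  n_win <- as.integer(round(window / dt))
  time <- tr$time
  rows <- lapply(seq_along(tr$ids), function(r) {
    id <- tr$ids[r]
    onsets <- which(tr$arrivals_exc[, r] > 0 & time >= from &
                      time <= max(time) - window)
    if (!length(onsets)) {
      return(tibble::tibble(neuron = id,
                            class = if (id <= sim$meta$n_rs) "RS" else "FS",
                            n_onsets = 0L, q_ampa = NA_real_,
                            q_nmda = NA_real_, ratio = NA_real_))
    }
    idx <- outer(onsets, 0:n_win, `+`)
    avg_ampa <- colMeans(matrix(tr$i_ampa[, r][idx], nrow = length(onsets)))
    avg_nmda <- colMeans(matrix(tr$i_nmda[, r][idx], nrow = length(onsets)))
    tgrid <- (0:n_win) * dt
    qa <- trapz_integral(tgrid, avg_ampa) / 1000
    qn <- trapz_integral(tgrid, avg_nmda) / 1000
    tibble::tibble(neuron = id,
                   class = if (id <= sim$meta$n_rs) "RS" else "FS",
                   n_onsets = length(onsets), q_ampa = qa, q_nmda = qn,
                   ratio = abs(qn) / abs(qa))
  })
  out <- do.call(rbind, rows)
  out$class <- factor(out$class, levels = c("RS", "FS"))
  out
}

#' Time-averaged population mean membrane potentials
#'
#' Averages the population mean potential (already averaged over neurons
#' at each sample by the engine) over time, after the transient. With a
#' list of simulations the mean and SEM across repeats are reported.
#'
#' @param sims a `gamma_sim` or a list of them (repeat simulations).
#' @param from start of the averaging window (ms); defaults to each
#'   run's transient.
#'
#' @return A tibble with one row per class: `class`, `mean_v` (mV),
#'   `sem` (NA for a single run), `n_sims`.
#' @export
mean_potentials <- function(sims, from = NULL) {
  if (inherits(sims, "gamma_sim")) sims <- list(sims)
  per_run <- vapply(sims, function(s) {
    f <- if (is.null(from)) s$meta$transient else from
    sel <- s$mean_v$time > f
    c(rs = mean(s$mean_v$rs[sel]), fs = mean(s$mean_v$fs[sel]))
  }, numeric(2))
  n <- length(sims)
  sem <- function(v) if (n > 1) stats::sd(v) / sqrt(n) else NA_real_
  tibble::tibble(class = factor(c("RS", "FS"), levels = c("RS", "FS")),
                 mean_v = c(mean(per_run["rs", ]), mean(per_run["fs", ])),
                 sem = c(sem(per_run["rs", ]), sem(per_run["fs", ])),
                 n_sims = n)
}
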