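test_that("Welch PSD localizes a pure sinusoid in its exact bin", {
  fs <- 1000
  t <- seq_len(4000) / fs
  x <- sin(2 * pi * 60 * t) # 60 Hz = 15 x the 4 Hz resolution
  psd <- welch_psd(x, fs)
  expect_equal(psd$freqs[2] - psd$freqs[1], 4)
  expect_equal(psd$peak_freq, 60)
  # almost all power concentrates in that bin
  expect_gt(psd$peak_power, 100 * stats::median(psd$power))
})

test_that("Welch PSD of white noise is flat and a constant has only DC power", {
  set.seed(99)
  x <- stats::rnorm(8000)
  psd <- welch_psd(x, 1000)
  expect_lt(max(psd$power[-1]), 5 * stats::median(psd$power[-1]))
  psd_c <- welch_psd(rep(3.7, 1000), 1000)
  expect_true(all(psd_c$power[-1] < 1e-20))
})

test_that("Welch integral recovers the signal variance (Parseval within windowing bias)", {
  set.seed(5)
  x <- as.numeric(stats::filter(stats::rnorm(20000), rep(1, 4), sides = 1))
  x <- x[!is.na(x)]
  psd <- welch_psd(x, 1000)
  total <- sum(psd$power) * (psd$freqs[2] - psd$freqs[1])
  expect_lt(abs(total - stats::var(x)) / stats::var(x), 0.1)
})

test_that("Welch estimator agrees with an external reference implementation", {
  # cross-check against scipy.signal.welch on a short fixture
  py <- Sys.which("python")
  expect_true(nzchar(py))
  set.seed(31)
  x <- stats::rnorm(1500) + sin(2 * pi * 40 * seq_len(1500) / 1000)
  fx <- tempfile(fileext = ".txt")
  fout <- tempfile(fileext = ".txt")
  writeLines(format(x, digits = 17), fx)
  script <- sprintf(
    "import numpy as np\nfrom scipy import signal\nx = np.loadtxt(%s)\nf, p = signal.welch(x, fs=1000, window='hamming', nperseg=250, noverlap=125)\nnp.savetxt(%s, np.column_stack([f, p]))\n",
    deparse(fx), deparse(fout))
  fpy <- tempfile(fileext = ".py")
  writeLines(script, fpy)
  status <- system2(py, fpy, stdout = FALSE, stderr = FALSE)
  expect_equal(status, 0L)
  ref <- utils::read.table(fout)
  psd <- welch_psd(x, 1000)
  expect_equal(psd$freqs, ref[[1]])
  expect_equal(psd$power, ref[[2]], tolerance = 1e-10)
  unlink(c(fx, fout, fpy))
})

test_that("Welch input validation names the minimum length", {
  expect_error(welch_psd(numeric(100), 1000), "250")
  expect_error(welch_psd(numeric(300), 1000, overlap = 250), "overlap")
})

test_that("state classification separates dominant peaks from flat spectra", {
  freqs <- seq(0, 500, by = 4)
  flat <- rep(1, length(freqs))
  mkpsd <- function(power) {
    structure(list(freqs = freqs, power = power,
                   peak_freq = freqs[which.max(power[-1]) + 1],
                   peak_power = max(power[-1]), fs = 1000,
                   n_segments = 10, normalized = FALSE),
              class = "psd_result")
  }
  # sharp 60 Hz peak 20x the baseline: gamma
  p <- flat
  p[freqs == 60] <- 20
  st <- classify_state(mkpsd(p))
  expect_equal(st$label, "gamma")
  expect_equal(st$peak_freq, 60)
  expect_gt(st$peak_prominence_ratio, 15)
  # flat spectrum: AI
  expect_equal(classify_state(mkpsd(flat))$label, "AI")
  # peak below the dominance threshold: AI
  p2 <- flat
  p2[freqs == 48] <- 3
  expect_equal(classify_state(mkpsd(p2), threshold = 5)$label, "AI")
  expect_equal(classify_state(mkpsd(p2), threshold = 2)$label, "gamma")
})

test_that("responsiveness follows its defining ratio and is antisymmetric", {
  mk <- function(times, classes = NULL, n_rs = 4000, n_fs = 1000) {
    if (is.null(classes)) classes <- rep("RS", length(times))
    structure(list(
      spikes = tibble::tibble(neuron = seq_along(times),
                              class = factor(classes, levels = c("RS", "FS")),
                              time = times),
      meta = list(n_rs = n_rs, n_fs = n_fs, graph_seed = 1L, drive_seed = 1L,
                  duration = 2000, dt = 0.1,
                  condition = c(q_nmda_rs = 0.8, q_nmda_fs = 1),
                  stimulus = list(amplitude = 1, sigma = 50, center = 1000,
                                  seed = 1L),
                  transient = 500)), class = "gamma_sim")
  }
  # identical records: R = 0
  a <- mk(c(900, 1000, 1100))
  r0 <- responsiveness(list(with = a, without = a), "all", T = 500)
  expect_equal(r0$R, 0)
  # direct substitution: 2500 extra spikes, T = 500 ms, N_n = 5000
  with <- mk(stats::runif(3000, 800, 1200))
  without <- mk(stats::runif(500, 800, 1200))
  r <- responsiveness(list(with = with, without = without), "all", T = 500)
  expect_equal(r$R, (3000 - 500) / (0.5 * 5000))
  expect_equal(r$R, 1)
  # one extra spike, N_n = 1 population: R = 2 Hz at T = 500
  w1 <- mk(c(950, 1010), n_rs = 1, n_fs = 1)
  o1 <- mk(1010, n_rs = 1, n_fs = 1)
  expect_equal(responsiveness(list(with = w1, without = o1), "RS",
                              T = 500)$R, 2)
  # antisymmetry under swapping the pair
  rev <- responsiveness(list(with = without, without = with), "all", T = 500)
  expect_equal(rev$R, -r$R)
  # mismatched metadata is refused
  bad <- with
  bad$meta$drive_seed <- 99L
  expect_error(responsiveness(list(with = bad, without = without)),
               "not comparable")
})

test_that("synaptic charge integrates the stated 10 ms window", {
  t <- seq(0, 50, by = 0.1)
  # constant 10 pA over the window: 0.1 pC
  expect_equal(synaptic_charge(t, rep(10, length(t)), onset = 20), 0.1)
  expect_equal(synaptic_charge(t, rep(0, length(t)), onset = 5), 0)
  # single-exponential AMPA current: matches the analytic integral within 1%
  tau <- 1.5
  cur <- ifelse(t >= 10, 5 * exp(-(t - 10) / tau) * (-65), 0)
  q_analytic <- 5 * (-65) * tau * (1 - exp(-10 / tau)) / 1000
  expect_equal(synaptic_charge(t, cur, onset = 10), q_analytic,
               tolerance = 0.01 * abs(q_analytic))
  # truncated window is an error
  expect_error(synaptic_charge(t, rep(1, length(t)), onset = 45), "window")
})

test_that("mean potentials average neurons then time, with SEM over repeats", {
  mk <- function(vrs, vfs) {
    structure(list(mean_v = tibble::tibble(time = 1:100,
                                           rs = rep(vrs, 100),
                                           fs = rep(vfs, 100)),
                   meta = list(transient = 0)), class = "gamma_sim")
  }
  one <- mean_potentials(mk(-60, -70))
  expect_equal(one$mean_v, c(-60, -70))
  expect_true(all(is.na(one$sem)))
  many <- mean_potentials(list(mk(-60, -70), mk(-62, -68)))
  expect_equal(many$mean_v, c(-61, -69))
  expect_equal(many$sem[1], stats::sd(c(-60, -62)) / sqrt(2))
})
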