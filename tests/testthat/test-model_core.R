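test_that("cell-class presets carry the expected structure and units", {
  rs <- rs_params()
  fs <- fs_params()
  # shared passive properties of the two classes
  for (p in list(rs, fs)) {
    expect_s3_class(p, "neuron_params")
    expect_equal(p$C, 150)
    expect_equal(p$g_L, 10)
    expect_equal(p$E_L, -65)
    expect_equal(p$V_rest, -65)
    expect_equal(p$T_ref, 5)
    expect_equal(p$tau_w, 500)
  }
  # class-distinguishing parameters
  expect_equal(rs$Delta, 2)
  expect_equal(fs$Delta, 0.5)
  expect_equal(fs$V_th, -47.5)
  expect_equal(rs$a, 4)
  expect_equal(rs$b, 20)
  expect_equal(fs$a, 0)
  expect_equal(fs$b, 0)
  # validation
  expect_error(neuron_params(C = -1, g_L = 10, E_L = -65, V_th = -50,
                             Delta = 2, a = 0, b = 0, tau_w = 500,
                             T_ref = 5, V_rest = -65), "C")
  expect_error(neuron_params(C = 150, g_L = 10, E_L = -65, V_th = -50,
                             Delta = 0, a = 0, b = 0, tau_w = 500,
                             T_ref = 5, V_rest = -65), "Delta")
})

test_that("adex_drift matches an independent evaluation of the membrane equations", {
  rs <- rs_params()
  # independent one-line evaluators of the two ODE right-hand sides
  f_v <- function(V, w, I, p) (-p$g_L * (V - p$E_L) +
    p$g_L * p$Delta * exp((V - p$V_th) / p$Delta) - w - I) / p$C
  f_w <- function(V, w, p) (p$a * (V - p$E_L) - w) / p$tau_w

  # at rest the exponential term is the only nonzero drift
  d <- adex_drift(neuron_state(V = -65), rs, I_syn = 0)
  expect_equal(d[["dw"]], 0)
  expect_equal(d[["dV"]], rs$g_L * rs$Delta * exp((-65 - rs$V_th) / rs$Delta) / rs$C)
  expect_lt(d[["dV"]], 1e-4) # near fixed point

  # FS: no subthreshold adaptation
  dfs <- adex_drift(neuron_state(V = -65), fs_params(), I_syn = 0)
  expect_identical(dfs[["dw"]], 0)

  # general states against the independent evaluator
  cases <- list(c(-55, 50, 0), c(-52, 120, -300), c(-70, -10, 250),
                c(-50.0001, 0, 0))
  for (cs in cases) {
    d <- adex_drift(neuron_state(V = cs[1], w = cs[2]), rs, I_syn = cs[3])
    expect_equal(d[["dV"]], f_v(cs[1], cs[2], cs[3], rs), tolerance = 1e-12)
    expect_equal(d[["dw"]], f_w(cs[1], cs[2], rs), tolerance = 1e-12)
  }
  expect_error(adex_drift(neuron_state(V = -60, w = 0) |>
                            (\(s) { s$V <- NaN; s })(), rs),
               "non-finite")
})

test_that("detect_and_reset applies threshold, reset, adaptation jump and refractoriness", {
  rs <- rs_params()
  st <- neuron_state(V = rs$V_th + 1, w = 10)
  out <- detect_and_reset(st, rs, t = 100)
  expect_true(out$spiked)
  expect_equal(out$state$V, -65)
  expect_equal(out$state$w, 30) # w + b
  expect_equal(out$state$refractory_until, 105)
  expect_equal(out$state$last_spike, 100)

  # below threshold: nothing happens
  fs <- fs_params()
  out2 <- detect_and_reset(neuron_state(V = -48), fs, t = 50)
  expect_false(out2$spiked)
  expect_equal(out2$state$V, -48)

  # a second crossing inside the refractory period is ignored
  st <- out$state
  st$V <- rs$V_th + 5 # hypothetical crossing at t = 103 < 105
  out3 <- detect_and_reset(st, rs, t = 103)
  expect_false(out3$spiked)

  # custom cut potential
  out4 <- detect_and_reset(neuron_state(V = -20), rs, t = 0, v_cut = -10)
  expect_false(out4$spiked)
})

test_that("an RS neuron at rest stays silent over long runs", {
  g <- build_graph(connectivity_spec(n_rs = 1, n_fs = 1, p = 0,
                                     n_ext = 0, seed = 1L))
  cfg <- sim_config(duration = 10000, transient = 0)
  sim <- run_network(g, cfg, drive_spec(mu_ext = 0))
  expect_equal(nrow(sim$spikes), 0)
})

test_that("FS above rheobase is periodic and matches a fine-dt reference within 2%", {
  # rheobase for the exponential IF: I = g_L (V_th - E_L) - g_L Delta
  fs <- fs_params()
  i_rh <- fs$g_L * (fs$V_th - fs$E_L) - fs$g_L * fs$Delta
  expect_equal(i_rh, 170)
  inj <- 400 # comfortably above rheobase

  g <- build_graph(connectivity_spec(n_rs = 1, n_fs = 1, p = 0,
                                     n_ext = 0, seed = 1L))
  cfg <- sim_config(duration = 2000, transient = 0)
  sim <- run_network(g, cfg, drive_spec(mu_ext = 0),
                     i_inject = c(0, inj))
  isi <- diff(sim$spikes$time[sim$spikes$neuron == 2])
  expect_gt(length(isi), 20)
  expect_lt(max(isi) - min(isi), 1e-9) # perfectly periodic (a = b = 0)

  ref <- ref_network_sim(1, 1, list(rs = cbind(integer(0), integer(0)),
                                    fs = cbind(integer(0), integer(0))),
                         dt = 0.01, duration = 500,
                         i_inject = c(0, inj))
  isi_ref <- diff(ref$spikes$time[ref$spikes$neuron == 2])
  expect_lt(abs(mean(isi) - mean(isi_ref)) / mean(isi_ref), 0.02)
})

test_that("the adaptation current decays with tau_w when spikes are absent", {
  g <- build_graph(connectivity_spec(n_rs = 1, n_fs = 1, p = 0,
                                     n_ext = 0, seed = 1L))
  cfg <- sim_config(duration = 1000, transient = 0)
  # FS has a = 0, so w decays as a pure exponential from w0
  sim <- run_network(g, cfg, drive_spec(mu_ext = 0),
                     w0 = c(0, 100), record_ids = 2L)
  wtr <- sim$traces$w[, 1]
  tt <- sim$traces$time
  fit <- stats::lm(log(wtr) ~ tt)
  tau_hat <- -1 / stats::coef(fit)[[2]]
  expect_lt(abs(tau_hat - 500) / 500, 0.01)
})

test_that("refractory contract holds in driven network runs", {
  g <- desk_graph(3L)
  cfg <- sim_config(duration = 800, transient = 0,
                    syn = synapse_params(q_ampa = 2.3 * 5, q_gabaa = 4.75 * 5))
  sim <- run_network(g, cfg, drive_spec(mu_ext = 10, q_ext_ampa = 4,
                                        seed = 4L),
                     i_inject = rep(300, 250), init_v = "random")
  expect_gt(nrow(sim$spikes), 50)
  by_n <- split(sim$spikes$time, sim$spikes$neuron)
  min_isi <- min(vapply(by_n, function(t) if (length(t) > 1) min(diff(t)) else Inf,
                        numeric(1)))
  expect_gte(min_isi, 5)
})
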