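# Plain-R reference integrator for small AdEx networks, written directly
# from the model equations and independent of the compiled engine. Used
# as the fine-time-step oracle in engine tests. Supports constant
# injected currents and fixed edge lists; no stochastic drive.
#
# edges: list with matrices `rs` and `fs` (columns pre, post; pre indices
# are class-local for fs, global for rs), delays uniform.
ref_network_sim <- function(n_rs, n_fs, edges, rs = rs_params(),
                            fs = fs_params(), syn = synapse_params(),
                            dt = 0.01, duration = 1000,
                            i_inject = numeric(n_rs + n_fs),
                            v0 = NULL) {
  n <- n_rs + n_fs
  cls <- rep(c("RS", "FS"), c(n_rs, n_fs))
  par <- function(f) ifelse(cls == "RS", rs[[f]], fs[[f]])
  C <- par("C"); gL <- par("g_L"); EL <- par("E_L"); Vth <- par("V_th")
  Delta <- par("Delta"); a <- par("a"); b <- par("b"); tw <- par("tau_w")
  Vr <- par("V_rest"); vcut <- Vth
  refrac_steps <- round(par("T_ref") / dt)
  n_steps <- round(duration / dt)
  d_steps <- round(syn$delay / dt)

  V <- if (is.null(v0)) EL else v0
  w <- numeric(n)
  refrac <- integer(n)
  g_a <- numeric(n); g_g <- numeric(n)
  s_src <- numeric(n_rs); x_src <- numeric(n_rs)
  # delayed arrival queues, indexed by absolute step
  qa <- vector("list", n_steps + d_steps + 1L)
  qg <- vector("list", n_steps + d_steps + 1L)
  qx <- vector("list", n_steps + d_steps + 1L)
  spikes_id <- integer(0); spikes_t <- numeric(0)

  rs_out <- split(edges$rs[, 2], edges$rs[, 1])
  fs_out <- split(edges$fs[, 2], edges$fs[, 1])

  # in-lists for the NMDA gating sums
  nmda_in <- vector("list", n)
  for (k in seq_len(nrow(edges$rs))) {
    p <- edges$rs[k, 2]
    nmda_in[[p]] <- c(nmda_in[[p]], edges$rs[k, 1])
  }

  for (s in seq_len(n_steps)) {
    # arrivals scheduled for this step
    arr_a <- numeric(n); arr_g <- numeric(n); arr_x <- numeric(n_rs)
    if (!is.null(qa[[s]])) for (p in qa[[s]]) arr_a[p] <- arr_a[p] + syn$q_ampa
    if (!is.null(qg[[s]])) for (p in qg[[s]]) arr_g[p] <- arr_g[p] + syn$q_gabaa
    if (!is.null(qx[[s]])) for (p in qx[[s]]) arr_x[p] <- arr_x[p] + 1

    # gating and conductance updates (old x in the s update)
    s_new <- s_src + (-s_src / syn$tau_decay_nmda +
                        syn$alpha * x_src * (1 - s_src)) * dt
    s_src <- pmin(pmax(s_new, 0), 1)
    x_src <- x_src - (x_src / syn$tau_rise_nmda) * dt + arr_x
    g_a <- g_a - (g_a / syn$tau_ampa) * dt + arr_a
    g_g <- g_g - (g_g / syn$tau_gabaa) * dt + arr_g

    S <- vapply(seq_len(n), function(i) {
      if (is.null(nmda_in[[i]])) 0 else sum(s_src[nmda_in[[i]]])
    }, numeric(1))
    qn <- ifelse(cls == "RS", syn$q_nmda_rs, syn$q_nmda_fs)
    B <- 1 / (1 + exp(-0.062 * V) * (syn$mg_out / 3.57))
    i_syn <- g_a * (V - syn$e_ampa) + g_g * (V - syn$e_gabaa) +
      qn * S * (V - syn$e_nmda) * B

    in_ref <- refrac > 0
    vexp <- pmin(V, vcut)
    dV <- (-gL * (V - EL) + gL * Delta * exp((vexp - Vth) / Delta) -
             w - i_syn + i_inject) / C
    dw <- (a * (V - EL) - w) / tw
    Vn <- V + dV * dt
    wn <- w + dw * dt
    # refractory clamp: V fixed at reset, w decays toward a(Vr - EL)
    Vn[in_ref] <- Vr[in_ref]
    wn[in_ref] <- w[in_ref] +
      ((a * (Vr - EL))[in_ref] - w[in_ref]) / tw[in_ref] * dt
    refrac[in_ref] <- refrac[in_ref] - 1L
    V <- Vn; w <- wn

    spk <- which(!in_ref & V >= vcut)
    for (i in spk) {
      spikes_id <- c(spikes_id, i)
      spikes_t <- c(spikes_t, s * dt)
      V[i] <- Vr[i]
      w[i] <- w[i] + b[i]
      refrac[i] <- refrac_steps[i]
      at <- s + d_steps
      if (at <= length(qa)) {
        if (i <= n_rs) {
          tg <- rs_out[[as.character(i)]]
          if (!is.null(tg)) qa[[at]] <- c(qa[[at]], tg)
          qx[[at]] <- c(qx[[at]], i)
        } else {
          tg <- fs_out[[as.character(i - n_rs)]]
          if (!is.null(tg)) qg[[at]] <- c(qg[[at]], tg)
        }
      }
    }
  }
  list(spikes = data.frame(neuron = spikes_id, time = spikes_t))
}

# Fine-dt scalar integration of the NMDA gating pair for a given
# presynaptic spike train; the oracle for step_nmda tests.
ref_nmda_trace <- function(spike_times, duration, dt = 0.001,
                           tau_rise = 2, tau_decay = 200, alpha = 0.5) {
  n <- round(duration / dt)
  s <- numeric(n); x <- numeric(n)
  sc <- tabulate(pmax(1, round(spike_times / dt)), nbins = n)
  si <- 0; xi <- 0
  for (k in seq_len(n)) {
    s_new <- si + (-si / tau_decay + alpha * xi * (1 - si)) * dt
    xi <- xi - (xi / tau_rise) * dt + sc[k]
    si <- min(max(s_new, 0), 1)
    s[k] <- si; x[k] <- xi
  }
  data.frame(time = seq_len(n) * dt, s = s, x = x)
}

# small helpers reused across test files
desk_graph <- function(seed) {
  build_graph(connectivity_spec(n_rs = 200, n_fs = 50, n_ext = 250,
                                seed = seed))
}

# miniature profile for fast experiment-driver smoke tests
tiny_profile <- function() {
  list(name = "tiny", n_rs = 200L, n_fs = 50L, n_ext = 250L,
       reps_sweep = 1L, dur_sweep = 1000,
       reps_traj = 1L, dur_traj = 1000,
       reps_resp = 1L, dur_resp = 1000,
       nmda_sum_every = 0.5)
}
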