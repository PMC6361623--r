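# Independent reference integration of a single model cell with deSolve
# (tolerance-controlled lsoda).  The right-hand side is assembled from the
# R-level gating laws, so it shares no code with the compiled fixed-step
# engine beyond the parameter tables.

ode_cell_oracle <- function(archetype, amp_pA, duration_ms, params = fx_params(),
                            step_start = 0, step_end = duration_ms,
                            out_dt = 0.025) {
  testthat::skip_if_not_installed("deSolve")
  tpl <- cell_template(archetype, params)
  ncomp <- length(tpl$c_nF)
  ch <- tpl$channels
  code_name <- names(fx_chan_codes)[match(ch$code, fx_chan_codes)]
  has_h <- code_name %in% c("na", "ca", "a", "na_fs")
  m_inst <- code_name == "na_fs"
  ca_gated <- code_name == "sahp"
  nch <- length(ch$code)
  # state: V (ncomp), per-channel m (unless instantaneous), h where present,
  # Ca pool
  m_idx <- integer(nch); h_idx <- integer(nch)
  off <- ncomp
  for (i in seq_len(nch)) {
    if (!m_inst[i]) { off <- off + 1; m_idx[i] <- off }
    if (has_h[i]) { off <- off + 1; h_idx[i] <- off }
  }
  ca_idx <- off + 1
  n_state <- ca_idx
  ca <- tpl$ca

  init <- numeric(n_state)
  init[seq_len(ncomp)] <- tpl$el
  for (i in seq_len(nch)) {
    g0 <- eval_gating(code_name[i], tpl$el[ch$comp[i] + 1],
                      ca = ca$floor, ca_floor = ca$floor)
    if (m_idx[i] > 0) init[m_idx[i]] <- g0$m_inf[1]
    if (h_idx[i] > 0) init[h_idx[i]] <- g0$h_inf[1]
  }
  init[ca_idx] <- if (ca$has == 1) ca$floor else 0

  p_exp <- c(na = 3, dr = 1, m = 2, ca = 2, nap = 1, a = 1, h = 1, sahp = 1,
             na_fs = 3, dr_fs = 4)

  rhs <- function(t, y, parms) {
    v <- y[seq_len(ncomp)]
    dy <- numeric(n_state)
    i_ion <- numeric(ncomp)
    ica_soma <- 0
    for (i in seq_len(nch)) {
      cmp <- ch$comp[i] + 1
      g <- eval_gating(code_name[i], v[cmp],
                      ca = max(y[ca_idx], ca$floor), ca_floor = ca$floor)
      m <- if (m_inst[i]) g$m_inf[1] else y[m_idx[i]]
      h <- if (has_h[i]) y[h_idx[i]] else 1
      gg <- ch$g_uS[i] * m^p_exp[[code_name[i]]] * h
      cur <- gg * (v[cmp] - ch$erev[i])
      i_ion[cmp] <- i_ion[cmp] + cur
      if (ca$has == 1 && code_name[i] == "ca" && ch$comp[i] == ca$comp) {
        ica_soma <- ica_soma + cur
      }
      if (m_idx[i] > 0) dy[m_idx[i]] <- (g$m_inf[1] - y[m_idx[i]]) / g$m_tau[1]
      if (h_idx[i] > 0) dy[h_idx[i]] <- (g$h_inf[1] - y[h_idx[i]]) / g$h_tau[1]
    }
    i_inj <- if (t >= step_start && t < step_end) amp_pA / 1000 else 0
    for (k in seq_len(ncomp)) {
      axial <- if (k == 1) {
        sum(tpl$gax_uS[-1] * (v[-1] - v[1]))
      } else {
        tpl$gax_uS[k] * (v[1] - v[k])
      }
      dy[k] <- (-tpl$gl_uS[k] * (v[k] - tpl$el[k]) - i_ion[k] + axial +
                  if (k == 1) i_inj else 0) / tpl$c_nF[k]
    }
    if (ca$has == 1) {
      influx <- max(0, -ca$k * ica_soma * ca$iconv)
      dy[ca_idx] <- influx - y[ca_idx] / ca$tau
    }
    list(dy)
  }

  times <- seq(0, duration_ms, by = out_dt)
  sol <- deSolve::lsoda(init, times, rhs, parms = NULL,
                        rtol = 1e-8, atol = 1e-10, maxsteps = 500000)
  list(t = sol[, 1], v = sol[, 2], sol = sol)
}

# spike times as upward -20 mV crossings with linear interpolation
ode_spike_times <- function(t, v, thresh = -20, refractory = 2) {
  up <- which(v[-1] >= thresh & v[-length(v)] < thresh)
  if (!length(up)) return(numeric(0))
  ts <- t[up] + (thresh - v[up]) / (v[up + 1] - v[up]) * (t[up + 1] - t[up])
  keep <- c(TRUE, diff(ts) > refractory)
  ts[keep]
}
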