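#' Build a cell archetype template
#'
#' Converts the declarative per-archetype description (geometry in um,
#' densities in mS/cm2, specific capacitance in uF/cm2) into the absolute
#' quantities used by the integrator: capacitance in nF, conductances in uS,
#' soma-rooted axial coupling in uS.  Compartments are cylinders; surface
#' area is the lateral area pi*d*L.
#'
#' @param archetype one of `"PN_A"`, `"PN_C"`, `"FSI"`.
#' @param params a [bl_params()] list.
#' @param dt integration step, ms.
#' @return An object of class `cell_template`.
#' @export
cell_template <- function(archetype = c("PN_A", "PN_C", "FSI"), params = bl_params(),
                          dt = 0.05) {
  archetype <- match.arg(archetype)
  cfg <- if (archetype == "FSI") params$cells$fsi else params$cells$pn
  comps <- cfg$compartments
  nm <- vapply(comps, function(cc) cc$name, "")
  area_cm2 <- vapply(comps, function(cc) pi * cc$diameter * cc$length * 1e-8, 0)
  c_nF <- cfg$specific_capacitance * area_cm2 * 1e3
  gl_uS <- vapply(comps, function(cc) cc$leak, 0) * area_cm2 * 1e3
  el <- rep(cfg$leak_reversal, length(comps))

  # axial conductance child <-> soma: half-cylinder resistances in series
  ra <- cfg$axial_resistivity   # Ohm-cm
  axial_half <- function(cc) ra * (cc$length * 1e-4 / 2) / (pi * (cc$diameter * 1e-4 / 2)^2)
  gax <- vapply(seq_along(comps), function(i) {
    if (i == 1) return(0)
    1e6 / (axial_half(comps[[1]]) + axial_half(comps[[i]]))
  }, 0)

  rev <- cfg$reversals
  fprox <- if (is.null(cfg$prox_fraction)) 1 else cfg$prox_fraction
  ch_comp <- integer(0); ch_code <- integer(0); ch_g <- numeric(0); ch_e <- numeric(0)
  add_chan <- function(i, name, dens) {
    ch_comp <<- c(ch_comp, i - 1L)
    ch_code <<- c(ch_code, .chan_codes[[name]])
    ch_g <<- c(ch_g, dens * area_cm2[i] * 1e3)
    ch_e <<- c(ch_e, .chan_erev(name, rev))
  }
  for (i in seq_along(comps)) {
    cc <- comps[[i]]
    for (name in names(cc$channels)) add_chan(i, name, cc$channels[[name]])
    for (name in names(cc$channels_proximal))
      add_chan(i, name, fprox * cc$channels_proximal[[name]])
    if (!is.null(cc$sahp)) {
      dens <- if (archetype == "PN_A") cc$sahp$pn_a else cc$sahp$pn_c
      add_chan(i, "sahp", dens)
    }
  }

  ca <- if (archetype == "FSI") {
    list(has = 0L, comp = 0L, tau = 1, k = 0, floor = 1e-10, iconv = 0)
  } else {
    cca <- params$cells$pn$calcium
    list(has = 1L, comp = 0L, tau = cca$tau, k = cca$influx_k,
         floor = cca$floor, iconv = 1e-6 / area_cm2[1])
  }

  tg <- cfg$synapse_targets
  structure(list(
    archetype = archetype, comp_names = nm,
    c_nF = c_nF, gl_uS = gl_uS, el = el, gax_uS = gax,
    area_cm2 = area_cm2,
    channels = list(comp = ch_comp, code = ch_code, g_uS = ch_g, erev = ch_e),
    ca = ca,
    syn_exc = match(tg$excitatory, nm) - 1L,
    syn_inh = match(tg$inhibitory, nm) - 1L,
    dt = dt
  ), class = "cell_template")
}

#' @export
print.cell_template <- function(x, ...) {
  cat(sprintf("<cell_template %s> %d compartments (%s), %d channel instances\n",
              x$archetype, length(x$c_nF), paste(x$comp_names, collapse = ", "),
              length(x$channels$code)))
  invisible(x)
}

#' Steady-state and time constant of a channel gate
#'
#' Direct evaluation of the model's gating laws: for each gating variable of
#' the named current, the voltage- (or calcium-) dependent steady state
#' `x_inf` and time constant `tau` (ms).  These R expressions are written
#' out independently of the compiled integrator tables and double as the
#' reference in the test suite.
#'
#' @param channel channel name (`na`, `dr`, `m`, `ca`, `nap`, `a`, `h`,
#'   `sahp`, `na_fs`, `dr_fs`).
#' @param v membrane potential(s), mV.
#' @param ca calcium pool value (only used by `sahp`).
#' @param ca_floor lower clamp applied inside the `sahp` log10.
#' @return data.frame with columns `v`, and per gate `m_inf`, `m_tau` (and
#'   `h_inf`, `h_tau` where the current inactivates).
#' @export
eval_gating <- function(channel, v, ca = NULL, ca_floor = 1e-10) {
  stopifnot(all(is.finite(v)))
  exprel <- function(x) ifelse(abs(x) < 1e-7, 1 - x / 2, x / (exp(x) - 1))
  out <- data.frame(v = v)
  sig <- function(v, half, k) 1 / (exp((v + half) / k) + 1)
  switch(channel,
    na = {
      am <- 0.4 * 7.2 * exprel(-(v + 30) / 7.2)
      bm <- 0.124 * 7.2 * exprel((v + 30) / 7.2)
      ah <- 0.03 * 1.5 * exprel(-(v + 45) / 1.5)
      bh <- 0.01 * 1.5 * exprel((v + 45) / 1.5)
      out$m_inf <- am / (am + bm); out$m_tau <- 0.6156 / (am + bm)
      out$h_inf <- sig(v, 50, 4); out$h_tau <- 0.6156 / (ah + bh)
    },
    dr = {
      a <- exp(-0.1144 * (v + 15)); b <- exp(-0.0801 * (v + 15))
      out$m_inf <- sig(v, 15, -11); out$m_tau <- 50 * b / (1 + a)
    },
    m = {
      a <- 0.016 * exp(-(v + 52.7) / 23); b <- 0.016 * exp((v + 52.7) / 18.8)
      out$m_inf <- sig(v, 52.7, -10.3); out$m_tau <- 1 / (a + b)
    },
    ca = {
      out$m_inf <- sig(v, 30, -11)
      out$m_tau <- 2.5 / (exp(-(v + 37.1) / 32.3) + exp((v + 37.1) / 32.3))
      out$h_inf <- sig(v, 12.6, 18.9); out$h_tau <- rep(420, length(v))
    },
    nap = {
      out$m_inf <- sig(v, 48, -5); out$m_tau <- 2.5 + 14 * exp(-(v + 40) / 10)
    },
    a = {
      out$m_inf <- sig(v, 50, -10); out$m_tau <- rep(2, length(v))
      out$h_inf <- sig(v, 85, 5); out$h_tau <- rep(20, length(v))
    },
    h = {
      a <- exp(0.0832 * (v + 75)); b <- exp(0.0333 * (v + 75))
      out$m_inf <- sig(v, 81, 8); out$m_tau <- b / (0.0081 * (1 + a))
    },
    sahp = {
      if (is.null(ca)) stop("sahp gating requires a calcium value")
      stopifnot(ca >= 0)
      L <- log10(max(ca, ca_floor))
      a <- 0.0048 / exp(-5 * L - 17.5); b <- 0.012 / exp(2 * L + 20)
      out$m_inf <- rep(a / (a + b), length(v)); out$m_tau <- rep(48, length(v))
    },
    na_fs = {
      vs <- v - 10   # depolarized shift: threshold near -45 mV
      am <- 0.1 * 10 * exprel(-(vs + 35) / 10); bm <- 4 * exp(-(vs + 60) / 18)
      ah <- 0.07 * exp(-(vs + 58) / 20); bh <- 1 / (exp(-0.1 * (vs + 28)) + 1)
      out$m_inf <- am / (am + bm); out$m_tau <- rep(0, length(v))
      out$h_inf <- ah / (ah + bh); out$h_tau <- 1 / (5 * (ah + bh))
    },
    dr_fs = {
      vs <- v - 10
      a <- 0.01 * 10 * exprel(-(vs + 34) / 10); b <- 0.125 * exp(-(vs + 44) / 80)
      out$m_inf <- a / (a + b); out$m_tau <- 1 / (5 * (a + b))
    },
    stop("unknown channel: ", channel)
  )
  out
}

#' Interspike-interval adaptation ratio
#'
#' Ratio of the last to the first interspike interval of a spike train,
#' the measure used to classify principal neurons as adapting
#' (ratio > cutoff) or continuous.
#'
#' @param spike_times spike times in ms (at least 3 spikes).
#' @param cutoff classification cutoff, default 1.5.
#' @return list with `ratio` and `class` (`"adapting"`/`"continuous"`);
#'   fewer than 3 spikes yields `ratio = NA` and `class = NA`.
#' @export
adaptation_ratio <- function(spike_times, cutoff = 1.5) {
  if (length(spike_times) < 3) return(list(ratio = NA_real_, class = NA_character_))
  isi <- diff(sort(spike_times))
  ratio <- isi[length(isi)] / isi[1]
  list(ratio = ratio, class = if (ratio > cutoff) "adapting" else "continuous")
}

#' Spike width at half amplitude
#'
#' Width of the first spike of a somatic voltage trace at the level halfway
#' between spike threshold (first point where dV/dt exceeds `dvdt_thresh`)
#' and the spike peak.
#'
#' @param t,v time (ms) and somatic voltage (mV), uniformly sampled.
#' @param dvdt_thresh slope criterion defining threshold, mV/ms.
#' @return width in ms, or `NA` if there is no spike.
#' @export
spike_halfwidth <- function(t, v, dvdt_thresh = 20) {
  dt <- t[2] - t[1]
  dv <- c(diff(v) / dt, 0)
  up <- which(v[-1] >= -20 & v[-length(v)] < -20)
  if (!length(up)) return(NA_real_)
  ipk_rel <- which.max(v[up[1]:min(up[1] + round(3 / dt), length(v))])
  ipk <- up[1] + ipk_rel - 1
  ith <- up[1]
  while (ith > 1 && dv[ith - 1] > dvdt_thresh) ith <- ith - 1
  half <- (v[ith] + v[ipk]) / 2
  i1 <- ith
  while (i1 < ipk && v[i1] < half) i1 <- i1 + 1
  i2 <- ipk
  while (i2 < length(v) && v[i2] > half) i2 <- i2 + 1
  if (i2 >= length(v)) return(NA_real_)
  # linear interpolation at both crossings
  f1 <- if (v[i1] == v[i1 - 1]) 0 else (half - v[i1 - 1]) / (v[i1] - v[i1 - 1])
  f2 <- if (v[i2] == v[i2 - 1]) 0 else (half - v[i2 - 1]) / (v[i2] - v[i2 - 1])
  ((i2 - 1 + f2) - (i1 - 1 + f1)) * dt
}

#' Simulate one isolated cell under current clamp
#'
#' Runs a single cell with background noise disabled; a somatic current
#' step can be applied after an equilibration period.
#'
#' @param archetype cell archetype name.
#' @param amp_pA somatic step amplitude in pA.
#' @param step_ms step duration in ms.
#' @param settle_ms equilibration time before the step.
#' @param tail_ms simulated time after the step ends.
#' @param params,dt model parameters and integration step.
#' @return list with every-step `t` (ms, 0 at step onset), somatic `v`,
#'   `spikes` (ms, same origin), and the full trace object.
#' @export
simulate_cell <- function(archetype, amp_pA = 0, step_ms = 500, settle_ms = 2000,
                          tail_ms = 0, params = bl_params(), dt = 0.05) {
  net <- single_cell_network(archetype, params)
  dur <- settle_ms + step_ms + tail_ms
  inj <- data.frame(cell = 1, comp = 1, start = settle_ms, end = settle_ms + step_ms,
                    amp_nA = amp_pA / 1000)
  tr <- simulate_network(net, duration = dur, seed = 1, dt = dt,
                         record_v = 1, v_every_step = TRUE, inj = inj,
                         background = FALSE)
  keep <- tr$t >= settle_ms - 300
  list(t = tr$t[keep] - settle_ms, v = tr$v[keep, 1],
       spikes = tr$spikes$t[tr$spikes$t >= settle_ms] - settle_ms, traces = tr)
}

#' Passive membrane properties of a model cell
#'
#' Equilibrates the cell, applies a small hyperpolarizing somatic step and
#' reports resting potential, input resistance and membrane time constant
#' (single-exponential fit of the charging curve).
#'
#' @param archetype cell archetype name.
#' @param amp_pA step amplitude (default -20 pA).
#' @param step_ms step duration.
#' @param params,dt model parameters and integration step.
#' @param settle_ms equilibration time; convergence to steady state is
#'   required within this window.
#' @return list with `v_rest` (mV), `r_in` (MOhm), `tau_m` (ms).
#' @export
measure_passive <- function(archetype = "PN_A", amp_pA = -20, step_ms = 500,
                            params = bl_params(), dt = 0.05, settle_ms = 3000) {
  sim <- simulate_cell(archetype, amp_pA = amp_pA, step_ms = step_ms,
                       settle_ms = settle_ms, params = params, dt = dt)
  pre <- sim$v[sim$t < 0]
  # steady state: drift over the last 200 ms of equilibration must be tiny
  i_back <- max(1L, length(pre) - round(200 / dt))
  drift <- abs(pre[length(pre)] - pre[i_back])
  if (!is.finite(drift) || drift > 0.05)
    stop("no steady state reached within ", settle_ms, " ms (drift ", signif(drift, 2), " mV)")
  v_rest <- pre[length(pre)]
  on <- sim$t >= 0 & sim$t < step_ms
  v_on <- sim$v[on]; t_on <- sim$t[on]
  n_ss <- round(0.2 * length(v_on))
  v_ss <- mean(v_on[(length(v_on) - n_ss):length(v_on)])
  r_in <- (v_ss - v_rest) / (amp_pA / 1000)   # mV / nA = MOhm
  # single-exponential fit (free asymptote) of the charging-curve onset;
  # the window excludes the slow voltage-dependent creep that follows the
  # passive charging phase
  win <- min(100, step_ms / 2)
  d <- data.frame(tt = t_on[t_on < win], vv = v_on[t_on < win])
  fit <- try(stats::nls(vv ~ a + b * exp(-tt / tau), data = d,
                        start = list(a = v_ss, b = v_rest - v_ss, tau = 25)),
             silent = TRUE)
  tau_m <- if (inherits(fit, "try-error")) {
    frac <- (d$vv - v_rest) / (v_ss - v_rest)
    d$tt[which(frac >= 0.632)[1]]    # 63% rise time as fallback
  } else {
    stats::coef(fit)[["tau"]]
  }
  list(v_rest = v_rest, r_in = r_in, tau_m = tau_m)
}

#' FSI spike width under a suprathreshold step
#'
#' @param archetype cell archetype (default FSI).
#' @param amp_pA step amplitude in pA.
#' @param params model parameters.
#' @return half-amplitude width of the first spike, ms (`NA` if no spike).
#' @export
fsi_spike_halfwidth <- function(archetype = "FSI", amp_pA = 200, params = bl_params()) {
  sim <- simulate_cell(archetype, amp_pA = amp_pA, step_ms = 500, params = params)
  if (!length(sim$spikes)) return(NA_real_)
  spike_halfwidth(sim$t, sim$v)
}


#' Current-clamp step protocol
#'
#' Runs a family of somatic current steps (the slice protocol: -200 to
#' +360 pA in 40-pA increments, 500 ms) on one archetype and reports the
#' spike count and adaptation ratio per step.
#'
#' @param archetype cell archetype name.
#' @param amplitudes_pA step amplitudes.
#' @param step_ms step duration.
#' @param params model parameters.
#' @return data.frame with `amp_pA`, `n_spikes`, `rate_hz`, `adaptation`.
#' @export
run_current_clamp <- function(archetype, amplitudes_pA = seq(-200, 360, by = 40),
                              step_ms = 500, params = bl_params()) {
  do.call(rbind, lapply(amplitudes_pA, function(a) {
    s <- simulate_cell(archetype, amp_pA = a, step_ms = step_ms, params = params)
    data.frame(amp_pA = a, n_spikes = length(s$spikes),
               rate_hz = length(s$spikes) / step_ms * 1000,
               adaptation = adaptation_ratio(s$spikes)$ratio)
  }))
}
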