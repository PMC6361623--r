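#' NMDA receptor magnesium block
#'
#' Voltage dependence of the NMDA conductance,
#' `s(V) = 1 / (1 + 0.33 exp(-0.06 V))`.
#'
#' @param v membrane potential, mV.
#' @return unblocked fraction in (0, 1), strictly increasing in `v`.
#' @export
mg_block <- function(v) 1 / (1 + 0.33 * exp(-0.06 * v))

#' Receptor rate constants from rise/decay time constants
#'
#' The receptor open fraction obeys
#' `r' = alphaT * ON * (1 - r) - beta * r` with a fixed-duration transmitter
#' pulse per presynaptic event.  The published tables give rise and decay
#' time constants; they identify `beta = 1/tau_decay` and the ON-phase time
#' constant `1/(alphaT + beta) = tau_rise`.
#'
#' @param tau_rise,tau_decay time constants, ms (`tau_decay > tau_rise`).
#' @return list with `alphaT` and `beta` (1/ms).
#' @export
receptor_rates <- function(tau_rise, tau_decay) {
  stopifnot(tau_decay > tau_rise, tau_rise > 0)
  list(alphaT = 1 / tau_rise - 1 / tau_decay, beta = 1 / tau_decay)
}

#' Advance a receptor state over one step
#'
#' Exact exponential update of the linear receptor ODE over `dt` given a
#' constant transmitter flag.  This is the reference (R) implementation of
#' the kinetics used per-synapse inside the compiled engine.
#'
#' @param r open fraction in `[0, 1]`.
#' @param on transmitter present (logical).
#' @param alphaT,beta rate constants, 1/ms.
#' @param dt step, ms.
#' @return updated open fraction.
#' @export
step_receptor <- function(r, on, alphaT, beta, dt) {
  stopifnot(r >= 0, r <= 1)
  if (on) {
    rinf <- alphaT / (alphaT + beta)
    rinf + (r - rinf) * exp(-(alphaT + beta) * dt)
  } else {
    r * exp(-beta * dt)
  }
}

#' Advance short-term plasticity state
#'
#' Two depression factors (fast/slow) and one facilitation factor; on a
#' presynaptic spike each factor is multiplied by its per-spike constant,
#' and between spikes each relaxes exponentially back toward 1.  The
#' conductance multiplier is `F * max(d1 * d2, d_min)`.
#'
#' @param state list with `d1`, `d2`, `F` (use [stp_init()] to create).
#' @param spike logical: did a presynaptic spike arrive this step?
#' @param pars list with `d1`, `d2` (per-spike multipliers, <= 1),
#'   `tau_d1`, `tau_d2`, `d_max_limit` (floor on the product), and
#'   optionally `f` (>= 1) and `tau_f`.
#' @param dt step, ms.
#' @return list with updated `state` and the conductance `multiplier`.
#' @export
step_stp <- function(state, spike, pars, dt) {
  rec <- function(x, tau) 1 + (x - 1) * exp(-dt / tau)
  state$d1 <- rec(state$d1, pars$tau_d1)
  state$d2 <- rec(state$d2, pars$tau_d2)
  f <- if (is.null(pars$f)) 1 else pars$f
  if (f != 1) state$F <- rec(state$F, pars$tau_f)
  if (spike) {
    state$d1 <- state$d1 * pars$d1
    state$d2 <- state$d2 * pars$d2
    if (f != 1) state$F <- state$F * f
  }
  mult <- state$F * max(state$d1 * state$d2, pars$d_max_limit)
  list(state = state, multiplier = mult)
}

#' @rdname step_stp
#' @export
stp_init <- function() list(d1 = 1, d2 = 1, F = 1)

#' Gap junction current
#'
#' Ohmic electrical coupling between two compartments: the current into
#' endpoint a is `g * (V_b - V_a)` and the current into b is its negative.
#'
#' @param v_a,v_b membrane potentials, mV.
#' @param g junctional conductance, nS.
#' @return list with `i_a` and `i_b` in pA (`nS * mV = pA`).
#' @export
gap_current <- function(v_a, v_b, g) {
  i_a <- g * (v_b - v_a)
  list(i_a = i_a, i_b = -i_a)
}

#' Calibrate the gap-junction conductance
#'
#' Finds the junctional conductance for which two resting model FSIs show a
#' given steady-state coupling coefficient (voltage deflection in the
#' unstimulated cell divided by the deflection in the injected cell).
#'
#' @param target_cc target coupling coefficient, in (0, 0.5).
#' @param params model parameters.
#' @param amp_pA probe current injected into cell A.
#' @param tol relative tolerance on the achieved coefficient.
#' @return conductance in nS.
#' @export
calibrate_gap_conductance <- function(target_cc = 0.05, params = bl_params(),
                                      amp_pA = -50, tol = 0.02) {
  if (target_cc <= 0) return(0)
  stopifnot(target_cc < 0.5)
  f <- function(g_nS) measure_coupling_coefficient(g_nS, params, amp_pA) - target_cc
  lo <- 1e-3; hi <- 5
  if (f(hi) < 0) stop("target coupling coefficient not bracketed")
  stats::uniroot(f, c(lo, hi), tol = tol * target_cc)$root
}

#' Measure the two-cell coupling coefficient
#'
#' @param g_nS junctional conductance.
#' @param params model parameters.
#' @param amp_pA probe current.
#' @return steady-state `dV_B / dV_A`.
#' @export
measure_coupling_coefficient <- function(g_nS, params = bl_params(), amp_pA = -50) {
  net <- two_fsi_network(g_nS, params)
  settle <- 1500; step <- 500
  inj <- data.frame(cell = 1, comp = 1, start = settle, end = settle + step,
                    amp_nA = amp_pA / 1000)
  tr <- simulate_network(net, duration = settle + step, seed = 1,
                         record_v = c(1, 2), inj = inj, background = FALSE)
  pre <- tr$t > settle - 100 & tr$t <= settle
  post <- tr$t > settle + step - 100 & tr$t <= settle + step
  dva <- mean(tr$v[post, 1]) - mean(tr$v[pre, 1])
  dvb <- mean(tr$v[post, 2]) - mean(tr$v[pre, 2])
  dvb / dva
}

# Build the engine-facing synapse class list (fixed order; 0-based ids used
# by edges are given by syn_class_id()).
.class_order <- c("pn_pn", "pn_fsi", "fsi_pn", "fsi_fsi", "aff_pn", "aff_fsi")

syn_class_id <- function(name) match(name, .class_order) - 1L

build_syn_classes <- function(params, dt) {
  sp <- params$synapses
  lapply(.class_order, function(nm) {
    cl <- sp$classes[[nm]]
    inh <- !is.null(cl$gaba)
    r1 <- if (inh) cl$gaba else cl$ampa
    k1 <- receptor_rates(r1$tau_rise, r1$tau_decay)
    out <- list(kind = if (inh) 1L else 0L,
                e_on1 = exp(-(k1$alphaT + k1$beta) * dt),
                rinf1 = k1$alphaT / (k1$alphaT + k1$beta),
                e_off1 = exp(-k1$beta * dt),
                g1_uS = r1$gmax / 1000,
                e_on2 = 1, rinf2 = 0, e_off2 = 1, g2_uS = 0,
                stp = 0L, dec1 = 1, dec2 = 1, sd1 = 1, sd2 = 1, dmin = 0,
                decf = 1, sf = 1)
    if (!inh && !is.null(cl$nmda)) {
      k2 <- receptor_rates(cl$nmda$tau_rise, cl$nmda$tau_decay)
      out$e_on2 <- exp(-(k2$alphaT + k2$beta) * dt)
      out$rinf2 <- k2$alphaT / (k2$alphaT + k2$beta)
      out$e_off2 <- exp(-k2$beta * dt)
      out$g2_uS <- cl$nmda$gmax / 1000
    }
    if (!is.null(cl$stp)) {
      out$stp <- 1L
      out$dec1 <- exp(-dt / cl$stp$tau_d1)
      out$dec2 <- exp(-dt / cl$stp$tau_d2)
      out$sd1 <- cl$stp$d1; out$sd2 <- cl$stp$d2
      out$dmin <- cl$stp$d_max_limit
      out$decf <- exp(-dt / cl$stp$tau_f)
      out$sf <- cl$stp$f
    }
    out
  })
}

# Draw synaptic weights for a connection class.  The published strength is
# (mean, spread); `strength_spread_is` selects whether the spread is an SD
# or a variance.  Weights are truncated below at trunc_frac * mean.
draw_weights <- function(n, strength, params) {
  mu <- strength[[1]]
  spread <- strength[[2]]
  sdv <- if (identical(params$synapses$strength_spread_is, "var")) sqrt(spread) else spread
  w <- stats::rnorm(n, mu, sdv)
  w <- pmax(w, params$synapses$trunc_frac * mu)
  # strength_role "distribution": the printed (mean, spread) describe the
  # weight distribution around the unitary conductance; weights are
  # normalized to mean 1 so the published "Conductance (nS)" is the mean
  # unitary conductance.  "multiplier": weights scale gmax directly.
  if (identical(params$synapses$strength_role, "distribution")) w <- w / mu
  w
}
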