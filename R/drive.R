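#' Synthetic instantaneous-rate profiles
#'
#' Builds a pool of naturalistic rate profiles standing in for in vivo
#' cortical unit recordings: each profile is an exponentiated
#' Ornstein-Uhlenbeck process (log-normal marginals, ~100-ms
#' autocorrelation time) sampled at 1-ms resolution and rescaled to a time
#' average of exactly 1 Hz.  These are synthetic fixtures; their parameters
#' live in the noise config.
#'
#' @param n_profiles number of profiles.
#' @param duration_ms profile length, ms.
#' @param params model parameters.
#' @param seed RNG seed (R RNG, restored afterwards).
#' @return list of numeric vectors (Hz at 1-ms bins, mean exactly 1).
#' @export
make_rate_profiles <- function(n_profiles, duration_ms, params = bl_params(),
                               seed = 1) {
  sg <- params$noise$surrogate
  tau <- sg$profile_ou_tau_ms; sdl <- sg$profile_ou_sd
  ef <- exp(-1 / tau); amp <- sdl * sqrt(1 - ef^2)
  withr_seed(seed, {
    lapply(seq_len(n_profiles), function(i) {
      x <- stats::filter(stats::rnorm(duration_ms, 0, amp), ef,
                         method = "recursive", init = stats::rnorm(1, 0, sdl))
      r <- exp(as.numeric(x))
      r / mean(r)
    })
  })
}

#' Surrogate afferent spike trains
#'
#' Each train pairs the temporal rate profile of one donor with the mean
#' rate of another (both drawn independently with replacement), then draws
#' a Poisson count in every 1-ms bin with
#' `lambda = profile * mean_rate * 1 ms`; spikes are placed uniformly
#' within their bin.
#'
#' @param profiles list of rate profiles (1-ms bins, mean 1).
#' @param rates_hz pool of donor mean rates, Hz.
#' @param n number of trains.
#' @param seed RNG seed.
#' @return list of `n` spike-time vectors (ms).
#' @export
surrogate_trains <- function(profiles, rates_hz, n, seed = 1) {
  if (!length(profiles) || !length(rates_hz)) stop("empty donor pool")
  withr_seed(seed, {
    lapply(seq_len(n), function(i) {
      pr <- profiles[[sample.int(length(profiles), 1)]]
      rate <- rates_hz[sample.int(length(rates_hz), 1)]
      lam <- pr * rate / 1000
      counts <- stats::rpois(length(lam), lam)
      idx <- rep.int(seq_along(counts), counts)
      sort((idx - 1) + stats::runif(length(idx)))
    })
  })
}

#' @rdname surrogate_trains
#' @details `draw_rate_pool()` draws donor mean rates from the configured
#'   log-normal pool (median 1-2 Hz with a heavy tail, emulating cortical
#'   unit rates in quiet wakefulness).
#' @param n_units pool size.
#' @param params model parameters.
#' @export
draw_rate_pool <- function(n_units, params = bl_params(), seed = 1) {
  lg <- params$noise$surrogate$rate_lognormal
  withr_seed(seed, stats::rlnorm(n_units, lg$meanlog, lg$sdlog))
}

#' Homogeneous Poisson spike trains
#'
#' @param rate_hz firing rate (scalar or per-train vector).
#' @param duration_ms train length.
#' @param n number of trains.
#' @param seed RNG seed.
#' @return list of spike-time vectors (ms).
#' @export
poisson_trains <- function(rate_hz, duration_ms, n, seed = 1) {
  rate_hz <- rep_len(rate_hz, n)
  withr_seed(seed, {
    lapply(seq_len(n), function(i) {
      k <- stats::rpois(1, rate_hz[i] * duration_ms / 1000)
      sort(stats::runif(k, 0, duration_ms))
    })
  })
}

#' One step of the Ornstein-Uhlenbeck background conductance
#'
#' Exact discretization:
#' `g(t+dt) = g0 + (g(t) - g0) exp(-dt/tau) + A N(0,1)` with
#' `A = sd * sqrt(1 - exp(-2 dt / tau))`, so the stationary distribution
#' has mean `g0` and standard deviation `sd` for any `dt`.
#'
#' @param g current conductance, nS.
#' @param g0 mean conductance, nS.
#' @param sd stationary standard deviation, nS.
#' @param tau correlation time, ms.
#' @param dt step, ms.
#' @param n1 standard-normal draw(s) (supply for reproducibility; default
#'   draws from R's RNG).
#' @return updated conductance (not clamped; clamping to zero happens where
#'   the conductance enters the membrane current).
#' @export
ou_step <- function(g, g0, sd, tau, dt, n1 = stats::rnorm(length(g))) {
  ef <- exp(-dt / tau)
  g0 + (g - g0) * ef + sd * sqrt(1 - ef^2) * n1
}

#' Background point-conductance current
#'
#' `I = ge (V - Ee) + gi (V - Ei)` with `Ee = 0`, `Ei = -75` mV;
#' conductances are floored at zero.
#'
#' @param g_e,g_i excitatory and inhibitory conductances, nS.
#' @param v membrane potential, mV.
#' @return current in pA (nS * mV).
#' @export
background_current <- function(g_e, g_i, v) {
  pmax(g_e, 0) * (v - 0) + pmax(g_i, 0) * (v + 75)
}
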