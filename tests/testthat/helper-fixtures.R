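# Shared fixtures, computed lazily and cached for the whole test session.

.fx <- new.env(parent = emptyenv())

fx_params <- function() {
  if (is.null(.fx$params)) .fx$params <- bl_params()
  .fx$params
}

# channel name -> code used by the compiled kinetics
fx_chan_codes <- c(na = 1, dr = 2, m = 3, ca = 4, nap = 5, a = 6, h = 7,
                   sahp = 8, na_fs = 9, dr_fs = 10)

# reduced 1,000-cell network + surrogate afferent drive (built once)
fx_reduced_net <- function() {
  if (is.null(.fx$net1000)) {
    rec <- reduced_recipe(1000, fx_params())
    .fx$net1000 <- build_network(rec, seed = 42)
  }
  .fx$net1000
}

fx_afferents <- function(duration_ms = 12000) {
  if (is.null(.fx$aff)) {
    net <- fx_reduced_net()
    .fx$aff <- surrogate_trains(make_rate_profiles(64, duration_ms, fx_params(), seed = 5),
                                draw_rate_pool(200, fx_params(), seed = 6),
                                net$n_afferents, seed = 7)
  }
  .fx$aff
}

# the spontaneous-activity reference run used by the gamma-related checks;
# shadow voltage-clamp recorders are attached to cells near the electrode
fx_gamma_run <- function() {
  if (is.null(.fx$gamma_run)) {
    net <- fx_reduced_net()
    center <- matrix(rep(net$box_um / 2, 3), 1)
    d <- sqrt((net$cells$x - center[1])^2 + (net$cells$y - center[2])^2 +
              (net$cells$z - center[3])^2)
    near_pn <- which(net$cells$type != "FSI" & d < 260)[1:60]
    near_fsi <- which(net$cells$type == "FSI" & d < 250)
    near_fsi <- near_fsi[seq_len(min(15, length(near_fsi)))]
    vc <- c(near_pn[!is.na(near_pn)], near_fsi)
    .fx$gamma_run <- simulate_network(net, 11000, seed = 1,
                                      afferent_trains = fx_afferents(),
                                      electrodes = center, vc_cells = vc)
    .fx$gamma_vc <- vc
  }
  .fx$gamma_run
}

fx_gamma_vc <- function() { fx_gamma_run(); .fx$gamma_vc }

# competition runs shared between the acceptance checks (3.5-s runs):
# random intermixed groups (fully overlapping FSI territory) and corner
# spheroids (spatially segregated), each under equal and unequal drive
fx_competition <- function() {
  if (is.null(.fx$comp)) {
    net <- fx_reduced_net()
    far1 <- rep(130, 3); far2 <- rep(net$box_um - 130, 3)
    .fx$comp <- list(
      ov_weak = run_competition(net, 5, 5, duration = 3500, seed = 9),
      ov_strong = run_competition(net, 20, 5, duration = 3500, seed = 9),
      sep_weak = run_competition(net, 5, 5, mode = "spheroid",
                                 centers = rbind(far1, far2), radius_um = 140,
                                 duration = 3500, seed = 9),
      sep_strong = run_competition(net, 20, 5, mode = "spheroid",
                                   centers = rbind(far1, far2), radius_um = 140,
                                   duration = 3500, seed = 9))
  }
  .fx$comp
}

# von Mises sampler (rejection from the wrapped density), independent of any
# package code
fx_rvonmises <- function(n, kappa) {
  out <- numeric(0)
  while (length(out) < n) {
    cand <- stats::runif(n, -pi, pi)
    keep <- stats::runif(n) < exp(kappa * (cos(cand) - 1))
    out <- c(out, cand[keep])
  }
  out[seq_len(n)]
}
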