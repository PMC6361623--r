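# Channel kinetics, passive properties and firing phenotypes of the three
# cell archetypes.

test_that("printed gating values are reproduced at anchor voltages", {
  # muscarinic K activation: sigmoid midpoint
  g <- eval_gating("m", -52.7)
  expect_equal(g$m_inf, 0.5, tolerance = 1e-12)
  # high-voltage Ca inactivation midpoint and fixed time constant
  g <- eval_gating("ca", -12.6)
  expect_equal(g$h_inf, 0.5, tolerance = 1e-12)
  expect_equal(g$h_tau, 420)
  # persistent Na: midpoint and tau from the printed expression
  g <- eval_gating("nap", -48)
  expect_equal(g$m_inf, 0.5, tolerance = 1e-12)
  expect_equal(g$m_tau, 2.5 + 14 * exp(-(-48 + 40) / 10), tolerance = 1e-12)
  expect_equal(g$m_tau, 33.6577, tolerance = 1e-4)
})

test_that("steady-state activation/inactivation curves are monotonic", {
  v <- seq(-120, 60, by = 0.5)
  inc <- function(x) expect_true(all(diff(x) > -1e-12))
  dec <- function(x) expect_true(all(diff(x) < 1e-12))
  for (ch in c("na", "dr", "m", "ca", "nap", "a", "h", "na_fs", "dr_fs")) {
    g <- eval_gating(ch, v)
    if (ch == "h") dec(g$m_inf) else inc(g$m_inf)   # H gate opens on hyperpolarization
    if (!is.null(g$h_inf)) dec(g$h_inf)
    expect_true(all(g$m_tau >= 0))
    if (!is.null(g$h_tau)) expect_true(all(g$h_tau > 0))
  }
  # delayed-rectifier tau stays positive over the full range as printed,
  # without clamping
  g <- eval_gating("dr", v)
  expect_true(all(g$m_tau > 0))
})

test_that("compiled gating matches the direct R evaluation", {
  v <- seq(-119.7, 59.7, by = 1.3)
  for (ch in c("na", "dr", "m", "ca", "nap", "a", "h", "na_fs", "dr_fs")) {
    r_ref <- eval_gating(ch, v)
    cpp <- blgamma:::cpp_gating_eval(fx_chan_codes[[ch]], v, 0, 1e-10)
    expect_equal(cpp$m_inf, r_ref$m_inf, tolerance = 1e-10)
    if (cpp$q > 0) expect_equal(cpp$h_inf, r_ref$h_inf, tolerance = 1e-10)
    if (!cpp$m_inst) expect_equal(cpp$m_tau, r_ref$m_tau, tolerance = 1e-10)
  }
  # Ca-gated sAHP across five decades of calcium
  for (ca in 10^seq(-9, -4)) {
    r_ref <- eval_gating("sahp", 0, ca = ca)
    cpp <- blgamma:::cpp_gating_eval(8L, 0, ca, 1e-10)
    expect_equal(cpp$m_inf[1], r_ref$m_inf[1], tolerance = 1e-10)
  }
  # sAHP activation increases with calcium and tolerates zero (floored)
  lo <- eval_gating("sahp", 0, ca = 0)$m_inf
  hi <- eval_gating("sahp", 0, ca = 1e-4)$m_inf
  expect_true(hi > lo)
  expect_true(is.finite(lo))
})

test_that("PN passive properties come out at the published operating point", {
  pp <- measure_passive("PN_A", params = fx_params())
  expect_equal(pp$v_rest, -70.3, tolerance = 0.01)     # relative: ~0.7 mV
  expect_equal(pp$r_in, 140, tolerance = 0.05)
  expect_equal(pp$tau_m, 30, tolerance = 0.08)
  # leak-only: equilibrium exactly at the leak reversal
  p0 <- fx_params()
  for (i in seq_along(p0$cells$pn$compartments)) {
    p0$cells$pn$compartments[[i]]$channels <- NULL
    p0$cells$pn$compartments[[i]]$channels_proximal <- NULL
    p0$cells$pn$compartments[[i]]$sahp <- NULL
  }
  pl <- measure_passive("PN_A", params = p0)
  expect_equal(pl$v_rest, -75, tolerance = 1e-6)
})

test_that("adaptation ratio classifies ISI patterns and the two PN types", {
  expect_equal(adaptation_ratio(c(0, 10, 20, 30))$ratio, 1)
  expect_equal(adaptation_ratio(c(0, 10, 20, 30))$class, "continuous")
  a <- adaptation_ratio(c(0, 10, 25, 45))  # first ISI 10, last 20
  expect_equal(a$ratio, 2)
  expect_equal(a$class, "adapting")
  expect_true(is.na(adaptation_ratio(c(1, 2))$ratio))

  sa <- simulate_cell("PN_A", amp_pA = 200, params = fx_params())
  sc <- simulate_cell("PN_C", amp_pA = 200, params = fx_params())
  ra <- adaptation_ratio(sa$spikes); rc <- adaptation_ratio(sc$spikes)
  expect_gt(ra$ratio, 1.5)
  expect_lte(rc$ratio, 1.5)
  expect_gt(ra$ratio, rc$ratio)  # the only parameter difference is the sAHP density
})

test_that("FSI spikes are brief and firing is non-adapting; PN spikes are broader", {
  hw <- fsi_spike_halfwidth(amp_pA = 200, params = fx_params())
  expect_lt(hw, 1)
  sp <- simulate_cell("PN_A", amp_pA = 300, params = fx_params())
  hw_pn <- spike_halfwidth(sp$t, sp$v)
  expect_gt(hw_pn, hw)
  hws <- c()
  for (amp in c(150, 200, 300)) {
    sf <- simulate_cell("FSI", amp_pA = amp, params = fx_params())
    expect_lte(adaptation_ratio(sf$spikes)$ratio, 1.1)
    hws <- c(hws, spike_halfwidth(sf$t, sf$v))
  }
  # half-width is stable over a twofold suprathreshold range
  expect_lt(diff(range(hws)) / mean(hws), 0.2)
})

test_that("fixed-step integration matches a tolerance-controlled reference ODE solution", {
  skip_if_not_installed("deSolve")
  # the staggered fixed-step scheme accumulates a small per-cycle timing
  # bias that compounds through an adapting train, so exact spike-time
  # agreement is asserted over the early train and the ISI sequence over
  # the whole step
  dur <- 250
  ref <- ode_cell_oracle("PN_A", amp_pA = 200, duration_ms = dur)
  ref_spk <- ode_spike_times(ref$t, ref$v)
  sim <- simulate_cell("PN_A", amp_pA = 200, step_ms = dur, settle_ms = 0,
                       params = fx_params())
  eng_spk <- sim$spikes
  expect_equal(length(eng_spk), length(ref_spk))
  expect_gte(length(ref_spk), 5)
  k <- seq_len(min(3, length(ref_spk)))
  expect_lt(max(abs(eng_spk[k] - ref_spk[k])), 0.5)
  isi_r <- diff(ref_spk); isi_e <- diff(eng_spk)
  expect_lt(max(abs(isi_e - isi_r) / isi_r), 0.05)
})


test_that("the current-clamp protocol summarizes the f-I relation", {
  fi <- run_current_clamp("PN_C", amplitudes_pA = c(-40, 120, 280),
                          params = fx_params())
  expect_equal(fi$n_spikes[1], 0)
  expect_gt(fi$n_spikes[3], fi$n_spikes[2])
  expect_true(all(fi$adaptation[fi$n_spikes >= 3] <= 1.5, na.rm = TRUE))
})
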