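# Line-source forward model, correction factors, electrode grids.

test_that("line-source potential has the right limits and scaling", {
  a <- c(0, 0, -15); b <- c(0, 0, 15)   # 30-um segment
  # zero current, zero potential
  expect_equal(line_source_potential(a, b, c(100, 0, 0), 0), 0)
  # far field matches a point source within 1%
  d <- 20 * 30
  phi_line <- line_source_potential(a, b, c(d, 0, 0), 1)
  phi_point <- 1e-3 / (4 * pi * 0.3 * d)   # mV for 1 nA at d um
  expect_equal(phi_line, phi_point, tolerance = 0.01)
  # linearity
  expect_equal(line_source_potential(a, b, c(50, 0, 20), 2),
               2 * line_source_potential(a, b, c(50, 0, 20), 1), tolerance = 1e-12)
  # subdividing the segment changes the potential by < 0.1%
  zs <- seq(-15, 15, length.out = 11)
  a10 <- cbind(0, 0, zs[-11]); b10 <- cbind(0, 0, zs[-1])
  phi10 <- line_source_potential(a10, b10, c(40, 0, 10), rep(0.1, 10))
  phi1 <- line_source_potential(a, b, c(40, 0, 10), 1)
  expect_equal(phi10, phi1, tolerance = 1e-3)
})

test_that("a single cell's far field falls at least as fast as a dipole", {
  # PN with a somatic spike: per-cell currents sum to ~0, so the summed
  # potential must decay faster than a monopole
  net <- single_cell_network("PN_A", fx_params())
  inj <- data.frame(cell = 1, comp = 1, start = 500, end = 520, amp_nA = 0.4)
  tr <- simulate_network(net, 700, seed = 1, inj = inj, record_imem = TRUE,
                         background = FALSE)
  spike_row <- which.max(abs(tr$imem[, 1]))
  cell_extent <- 600   # um, soma plus both dendrites
  dists <- cell_extent * c(5, 10, 20)
  phis <- vapply(dists, function(d) {
    lf <- compute_lfp(tr, net, matrix(c(d, 0, 0), 1))
    abs(lf$phi[spike_row, 1])
  }, 0)
  # decay exponent between successive distances at least ~2
  expon <- -diff(log(phis)) / diff(log(dists))
  expect_true(all(expon > 1.8))
})

test_that("near-soma extracellular spike is negative and decays with distance", {
  net <- single_cell_network("PN_A", fx_params())
  inj <- data.frame(cell = 1, comp = 1, start = 500, end = 520, amp_nA = 0.4)
  tr <- simulate_network(net, 700, seed = 1, inj = inj, record_imem = TRUE,
                         background = FALSE)
  lats <- c(30, 60, 120, 240, 480)
  el <- cbind(lats, 0, 0)
  lf <- compute_lfp(tr, net, el)
  win <- tr$t_ms >= 500 & tr$t_ms <= 540
  amp <- apply(lf$phi[win, ], 2, function(x) max(abs(x)))
  expect_lt(min(lf$phi[win, 1]), 0)            # negativity near the soma
  expect_true(all(diff(amp) < 0))              # monotone decay laterally
  fit <- stats::lm(log(amp) ~ lats)
  expect_gt(summary(fit)$r.squared, 0.8)       # near-exponential falloff
})

test_that("on-line LFP accumulation equals the after-the-fact superposition", {
  net <- make_fixtures("fifty_cell_net", seed = 4, params = fx_params())
  el <- matrix(c(net$box_um / 2, net$box_um / 2, net$box_um / 2,
                 net$box_um / 4, net$box_um / 2, net$box_um / 2), 2, 3, byrow = TRUE)
  tr <- simulate_network(net, 500, seed = 6, electrodes = el, record_imem = TRUE,
                         lfp_scale = 1)
  lf <- compute_lfp(tr, net, el, scale = 1)
  expect_equal(unclass(tr$lfp), unclass(lf$phi), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("density correction reproduces the printed factor range and default", {
  expect_equal(density_correction(2.5e4, 9840, 0.67), 1.9, tolerance = 0.02)
  expect_equal(density_correction(2e5, 9840, 0.67), 7.5, tolerance = 0.02)
  expect_equal(density_correction(9840, 9840), 1)
  expect_equal(default_lfp_correction(9840), 4.7, tolerance = 0.02)
})

test_that("the electrode grid matches the published layout", {
  g <- electrode_grid(1400, n = 9, spacing = 125, margin = 200)
  expect_equal(nrow(g), 729)
  expect_equal(attr(g, "dims"), c(9, 9, 9))
  ax <- sort(unique(g[, 1]))
  expect_equal(diff(ax), rep(125, 8))
  expect_equal(max(g) - min(g), 1000)            # spans 1,000 um
  expect_gte(min(g), 200); expect_lte(max(g), 1200)
  expect_error(electrode_grid(500, n = 9, spacing = 125), "does not fit")
})

test_that("edge correction is unity for homogeneous grids and inverts attenuation", {
  set.seed(21)
  n_el <- 5
  tt <- seq_len(12000) / 1000
  base <- function() {
    x <- stats::rnorm(12000)
    bf <- signal::butter(2, c(2, 200) / 500, "pass")
    signal::filtfilt(bf, x) + 3 * sin(2 * pi * 70 * tt) * (1 + 0.3 * sin(2 * pi * 0.5 * tt))
  }
  hom <- vapply(seq_len(n_el), function(i) base(), numeric(12000))
  f_hom <- edge_correction(hom, center = 3)
  expect_equal(f_hom, rep(1, n_el), tolerance = 0.1)
  # halve the gamma component on the two edge electrodes
  att <- hom
  for (j in c(1, n_el)) {
    x <- stats::rnorm(12000)
    bf <- signal::butter(2, c(2, 200) / 500, "pass")
    att[, j] <- signal::filtfilt(bf, x) +
      1.5 * sin(2 * pi * 70 * tt) * (1 + 0.3 * sin(2 * pi * 0.5 * tt))
  }
  f_att <- edge_correction(att, center = 3)
  # brute-force oracle: recompute the gamma-fraction ratio directly
  oracle <- vapply(c(1, n_el), function(j) {
    ps_j <- welch_psd(att[, j], 1000); ps_c <- welch_psd(att[, 3], 1000)
    gfrac <- function(ps) {
      fit <- fit_power_law(ps$freq, ps$power, exclude = c(45, 105))
      inb <- ps$freq >= 60 & ps$freq <= 80
      sum(pmax(ps$power[inb] - fit$a * ps$freq[inb]^(-fit$alpha), 0)) / sum(ps$power)
    }
    gfrac(ps_j) / gfrac(ps_c)
  }, 0)
  expect_equal(f_att[c(1, n_el)], oracle, tolerance = 1e-6)
  expect_true(all(f_att[c(1, n_el)] < 0.9))
})


test_that("the amplitude-versus-count exponent estimator runs on subsamples", {
  net <- make_fixtures("fifty_cell_net", seed = 4, params = fx_params())
  el <- rep(net$box_um / 2, 3)
  tr <- simulate_network(net, 1200, seed = 8, record_imem = TRUE)
  est <- estimate_density_exponent(tr, net, el,
                                   fractions = c(0.3, 0.6, 1), seed = 2)
  expect_length(est$sd, 3)
  expect_true(is.finite(est$exponent))
  # more cells, more LFP power
  expect_gt(est$sd[3], est$sd[1])
})
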