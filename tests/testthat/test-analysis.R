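# Spectral analysis, burst detection, entrainment and coherence.

test_that("Welch spectrum concentrates power at a tone and Morlet grid is quarter-octave", {
  fs <- 1000
  t <- seq_len(8000) / fs
  x <- sin(2 * pi * 40 * t) + 0.1 * stats::rnorm(length(t))
  ps <- welch_psd(x, fs)
  expect_equal(ps$freq[which.max(ps$power)], 40, tolerance = 0.06)
  ms <- morlet_spectrogram(x, fs)
  expect_equal(ms$freq, 2^seq(0, 8, 0.25))
  expect_true(all(ms$amplitude >= 0))
  mean_amp <- colMeans(ms$amplitude[1000:7000, ])
  expect_equal(ms$freq[which.max(mean_amp)], 2^(0.25 * round(log2(40) / 0.25)),
               tolerance = 0.1)
})

test_that("band phase advances linearly for a pure in-band tone", {
  fs <- 1000
  t <- seq_len(6000) / fs
  x <- sin(2 * pi * 70 * t)
  bp <- band_phase(x, fs, c(60, 80), order = 2)
  mid <- 500:5500
  amp <- bp$amplitude[mid]
  expect_lt(stats::sd(amp) / mean(amp), 0.02)
  dphi <- diff(bp$phase[mid])
  dphi[dphi < -pi] <- dphi[dphi < -pi] + 2 * pi
  expect_equal(mean(dphi), 2 * pi * 70 / fs, tolerance = 0.01)
  # zero-phase property: filtering the time-reversed signal equals the
  # time-reversed filtered signal (away from the edge transients)
  set.seed(1)
  y <- stats::rnorm(3000)
  bf <- signal::butter(2, c(60, 80) / (fs / 2), "pass")
  f1 <- signal::filtfilt(bf, y)
  f2 <- rev(signal::filtfilt(bf, rev(y)))
  mid <- 300:2700
  expect_equal(f1[mid], f2[mid], tolerance = 1e-6)
  # chirp: envelope maximal inside the band, attenuated two octaves out
  f_inst <- seq(10, 300, length.out = length(t))
  chirp <- sin(2 * pi * cumsum(f_inst) / fs)
  bc <- band_phase(chirp, fs, c(60, 80), order = 4)
  env_at <- function(f0) mean(bc$amplitude[abs(f_inst - f0) < 3])
  expect_gt(env_at(70), 0.9)
  expect_lt(env_at(70 / 4) / env_at(70), 0.1)
  expect_lt(env_at(280) / env_at(70), 0.1)
})

test_that("single-electrode burst detection recovers constructed bursts", {
  fs <- 1000
  t <- seq_len(20000) / fs
  # a signal with constant envelope: no events (smooth onset/offset so the
  # zero-phase filter has no edge transients)
  taper <- pmin(1, pmin(seq_along(t), rev(seq_along(t))) / 500)
  flat <- taper * sin(2 * pi * 70 * t)
  expect_equal(nrow(detect_bursts(flat, fs)), 0)
  # constant baseline envelope + one Gaussian burst: exactly one event
  # whose duration equals the injected envelope's 25%-of-peak span
  sig_t <- 0.04
  env <- exp(-(t - 10)^2 / (2 * sig_t^2))
  x1 <- (1 + 5 * env) * sin(2 * pi * 70 * t)
  b1 <- detect_bursts(x1, fs)
  expect_equal(nrow(b1), 1)
  # envelope 1 + 5 g(t) crosses 0.25 * (1 + 5) when g(t) = 0.1
  span <- 2 * sqrt(-2 * log(0.1)) * sig_t * 1000
  expect_equal(b1$duration, span, tolerance = 0.05)
  expect_equal(b1$peak_t, 10000, tolerance = 0.01)
  # two bursts 500 ms apart: two ordered events; amplitude-scale invariance
  env2 <- exp(-(t - 14.5)^2 / (2 * sig_t^2))
  x2 <- (1 + 5 * env + 5 * env2) * sin(2 * pi * 70 * t)
  b2 <- detect_bursts(x2, fs)
  expect_equal(nrow(b2), 2)
  expect_lt(b2$peak_t[1], b2$peak_t[2])
  b2s <- detect_bursts(17.3 * x2, fs)
  expect_equal(b2s$onset, b2$onset)
  expect_equal(b2s$peak_z, b2$peak_z, tolerance = 1e-9)
})

test_that("the amplitude-duration map segments power at watershed minima", {
  # monotone ramp: a single segment
  ramp <- seq(0, 1, length.out = 2000)
  m1 <- burst_amplitude_duration_map(ramp)
  expect_equal(nrow(m1$bursts), 1)
  # a single isolated peak: one segment covering the series
  t <- seq_len(3000)
  pk <- exp(-(t - 1500)^2 / (2 * 100^2))
  m2 <- burst_amplitude_duration_map(pk)
  expect_equal(nrow(m2$bursts), 1)
  # several peaks: percentile ranks uniform by construction
  set.seed(3)
  x <- abs(band_phase(stats::rnorm(20000), 1000, c(60, 80), 4)$amplitude)^2
  m3 <- burst_amplitude_duration_map(x)
  expect_gt(nrow(m3$bursts), 20)
  pr <- m3$bursts$percentile
  expect_equal(mean(pr), 50, tolerance = 0.1)
  expect_lt(max(pr), 100 + 1e-9)
  # segments partition the series: durations sum to its length
  expect_equal(sum(m3$bursts$duration), length(x))
})

test_that("4-D watershed recovers constructed spatiotemporal bursts exactly", {
  # one stationary blob
  g1 <- synthetic_gamma_grid(n = 7, duration_ms = 1200,
                             bursts = data.frame(t0 = 600, x0 = 4, y0 = 4, z0 = 4,
                                                 vx = 0, amp = 4, sigma_t = 50,
                                                 sigma_s = 1.2),
                             noise_sd = 0.05, seed = 4)
  d1 <- detect_bursts_4d(g1$z, spacing_um = 125)
  expect_equal(nrow(d1$bursts), 1)
  expect_equal(d1$bursts$peak_z, 4, tolerance = 0.1)
  # volume equals the brute-force count of member sites
  mem <- d1$members[[1]]
  expect_equal(d1$bursts$volume, nrow(unique(mem[, c("x", "y", "z")])))
  expect_lt(d1$bursts$net_displacement_um, 100)  # stationary blob stays put
  # translating blob: smooth enough that inter-voxel saddles stay below one
  # discretization bin, so the ridge floods as a single event
  shift_units <- 3
  dur_visible <- 2 * sqrt(-2 * log(0.25)) * 60   # 25%-of-peak time span
  g2 <- synthetic_gamma_grid(n = 9, duration_ms = 1200,
                             bursts = data.frame(t0 = 600, x0 = 3.5, y0 = 5, z0 = 5,
                                                 vx = shift_units / dur_visible,
                                                 amp = 4, sigma_t = 60, sigma_s = 2.5),
                             noise_sd = 0.05, seed = 5)
  d2 <- detect_bursts_4d(g2$z, spacing_um = 125)
  expect_equal(nrow(d2$bursts), 1)
  expect_equal(d2$bursts$net_displacement_um, shift_units * 125, tolerance = 0.35)
  expect_gte(d2$bursts$path_um, d2$bursts$net_displacement_um - 1e-9)
  expect_gt(d2$bursts$net_displacement_um,
            d1$bursts$net_displacement_um)     # translating vs stationary
  expect_equal(d2$bursts$speed, d2$bursts$path_um / d2$bursts$duration,
               tolerance = 1e-9)
  # two blobs disjoint in space and time: two events
  g3 <- synthetic_gamma_grid(n = 7, duration_ms = 1500,
                             bursts = data.frame(t0 = c(400, 1100),
                                                 x0 = c(2, 6), y0 = c(2, 6),
                                                 z0 = c(2, 6), vx = 0, amp = 4,
                                                 sigma_t = 40, sigma_s = 1.3),
                             noise_sd = 0.03, seed = 6)
  d3 <- detect_bursts_4d(g3$z, spacing_um = 125)
  expect_equal(nrow(d3$bursts), 2)
})

test_that("burst-peak PLV distinguishes locked from independent grids", {
  g <- synthetic_gamma_grid(n = 5, duration_ms = 600,
                            bursts = data.frame(t0 = 300, x0 = 3, y0 = 3, z0 = 3,
                                                vx = 0, amp = 4, sigma_t = 40,
                                                sigma_s = 1.2),
                            noise_sd = 0.04, seed = 12)
  tt <- seq_len(600)
  common <- 2 * pi * ((70 * tt / 1000) %% 1) - pi
  locked <- array(rep(common, each = 125), c(5, 5, 5, 600))
  set.seed(13)
  indep <- array(stats::runif(125 * 600, -pi, pi), c(5, 5, 5, 600))
  d_lock <- detect_bursts_4d(g$z, spacing_um = 125, phase = locked)
  d_ind <- detect_bursts_4d(g$z, spacing_um = 125, phase = indep)
  expect_equal(d_lock$bursts$plv[1], 1, tolerance = 1e-6)
  expect_lt(d_ind$bursts$plv[1], 0.3)
})

test_that("watershed membership partitions suprathreshold voxels", {
  g <- synthetic_gamma_grid(n = 5, duration_ms = 400,
                            bursts = data.frame(t0 = c(150, 280), x0 = c(2, 4),
                                                y0 = c(2, 4), z0 = c(2, 4), vx = 0,
                                                amp = c(3.5, 4), sigma_t = 30,
                                                sigma_s = 0.9),
                            noise_sd = 0.05, seed = 7)
  d <- detect_bursts_4d(g$z, spacing_um = 125)
  all_members <- do.call(rbind, d$members)
  key <- with(all_members, paste(x, y, z, t))
  expect_equal(anyDuplicated(key), 0)   # no voxel in two events
})

test_that("entrainment statistics match circular-statistics closed forms", {
  # identical phases
  e1 <- entrainment(rep(1.3, 50))
  expect_equal(e1$rv, 1); expect_equal(e1$ppc, 1)
  # uniform phases: RV small, PPC centered on zero
  set.seed(8)
  ppcs <- replicate(200, entrainment(stats::runif(40, -pi, pi))$ppc)
  expect_lt(abs(mean(ppcs)), 0.01)
  e2 <- entrainment(seq(-pi, pi, length.out = 1001)[-1])
  expect_lt(e2$rv, 0.01)
  # von Mises kappa = 1: RV -> I1(k)/I0(k) ~ 0.4463
  set.seed(9)
  th <- fx_rvonmises(4000, 1)
  e3 <- entrainment(th)
  expect_equal(e3$rv, besselI(1, 1) / besselI(1, 0), tolerance = 0.07)
  expect_equal(e3$rv, 0.4464, tolerance = 0.07)
  # PPC ~ RV^2 asymptotically
  expect_equal(e3$ppc, e3$rv^2, tolerance = 0.02)
  # sentinels
  expect_true(is.na(entrainment(1.2)$ppc))
  expect_true(is.na(entrainment(stats::runif(5))$rv))
  expect_false(is.na(entrainment(stats::runif(5))$ppc))
})

test_that("unbiased PLV is near zero for independent channels and one for locked ones", {
  set.seed(10)
  locked <- matrix(rep(stats::runif(500, -pi, pi), 4), 500, 4)
  expect_equal(plv_unbiased(locked), 1, tolerance = 1e-9)
  indep <- matrix(stats::runif(2000, -pi, pi), 500, 4)
  expect_lt(plv_unbiased(indep), 0.25)
  # expectation of the corrected square is ~0: average over replicates
  vals <- replicate(100, {
    m <- matrix(stats::runif(200, -pi, pi), 50, 4)
    ph <- m
    nc <- 4; acc <- 0; np <- 0
    for (a in 1:3) for (b in (a + 1):4) {
      p2 <- Mod(mean(exp(1i * (ph[, a] - ph[, b]))))^2
      acc <- acc + (50 * p2 - 1) / 49; np <- np + 1
    }
    acc / np
  })
  expect_lt(abs(mean(vals)), 0.02)
})

test_that("spike coherence is 1 for identical trains and localizes known lags", {
  set.seed(11)
  a <- sort(stats::runif(1500, 0, 5e4))
  sc <- spike_coherence(a, a, 5e4)
  expect_equal(max(Mod(sc$coherence)), 1, tolerance = 1e-9)
  expect_equal(min(Mod(sc$coherence)), 1, tolerance = 1e-9)
  i1 <- sort(stats::runif(1500, 0, 5e4)); i2 <- sort(stats::runif(1500, 0, 5e4))
  sci <- spike_coherence(i1, i2, 5e4)
  expect_lt(stats::quantile(Mod(sci$coherence), 0.95), 0.2)
  # jittered copy at +4 ms: corrected cross-correlation peaks at 4 ms
  b <- a + 4 + stats::rnorm(length(a), 0, 2)
  b <- sort(b[b > 0 & b < 5e4])
  scj <- spike_coherence(a, b, 5e4)
  expect_equal(scj$lags[which.max(scj$corrected)], 4, tolerance = 1e-9)
  # empty train sentinel
  expect_null(spike_coherence(numeric(0), a, 5e4)$coherence)
})
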