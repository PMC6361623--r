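#' Automated background-noise rebalancing
#'
#' Iteratively scales the Ornstein-Uhlenbeck background sources so that the
#' population firing rates match given targets (used to hold rates at their
#' unperturbed values after circuit manipulations, and to match in vivo
#' rates in the intact model).
#'
#' @param network a `bl_network`.
#' @param afferent_trains afferent drive for the probe runs.
#' @param targets named vector `c(pn = , fsi = )`, Hz.
#' @param start starting scale list (`pn_i`, `fsi_i`, ...).
#' @param duration probe-run length, ms (rates measured after 1 s).
#' @param seed probe seed.
#' @param tol relative tolerance on both rates.
#' @param max_iter iteration cap; on non-convergence the best scales found
#'   are returned with `converged = FALSE` and a warning.
#' @return list with `scale`, `rates`, `converged`.
#' @export
rebalance_noise <- function(network, afferent_trains, targets,
                            start = list(), duration = 3000, seed = 1,
                            tol = 0.1, max_iter = 8) {
  sc <- list(pn_e = 1, pn_i = 1, fsi_e = 1, fsi_i = 1)
  sc[names(start)] <- start
  best <- NULL; best_err <- Inf
  for (it in seq_len(max_iter)) {
    tr <- simulate_network(network, duration, seed + it,
                           afferent_trains = afferent_trains, noise_scale = sc)
    pr <- population_rates(tr, network, from = min(1000, duration / 2))
    pn <- sum(pr$rate_hz[1:2] * pr$n[1:2]) / sum(pr$n[1:2])
    fs <- pr$rate_hz[3]
    err <- max(abs(pn - targets[["pn"]]) / targets[["pn"]],
               abs(fs - targets[["fsi"]]) / targets[["fsi"]])
    if (err < best_err) { best <- list(scale = sc, rates = c(pn = pn, fsi = fs)); best_err <- err }
    if (err < tol) return(c(best, converged = TRUE))
    # inhibitory sources steer the rates; damped multiplicative update
    sc$pn_i <- min(max(sc$pn_i * (pn / targets[["pn"]])^0.6, 0.1), 12)
    sc$fsi_i <- min(max(sc$fsi_i * (fs / targets[["fsi"]])^0.6, 0.1), 12)
  }
  warning("noise rebalancing did not converge to ", tol * 100, "% (best ",
          round(best_err * 100), "%); proceeding with best scales")
  c(best, converged = FALSE)
}

#' Connection-ablation experiment
#'
#' Removes one connection class (for FSI-FSI, both chemical synapses and
#' gap junctions), optionally rebalances the background noise to the
#' baseline rates, runs the network, and reports the LFP power spectrum,
#' per-archetype entrainment (pairwise phase consistency) over a frequency
#' ladder, and the PN-population-burst-triggered FSI rate (bursts = 1-ms
#' bins where the PN population rate exceeds its 75th percentile).
#'
#' @param network a `bl_network`.
#' @param ablate one of `"none"`, `"fsi_pn"`, `"pn_fsi"`, `"fsi_fsi"`,
#'   `"pn_pn"`.
#' @param duration run length, ms (a 1-s settling period is discarded).
#' @param seed run seed.
#' @param afferent_trains afferent drive.
#' @param noise_scale baseline noise scales (list) or `NULL`.
#' @param rebalance_to rates (`c(pn=, fsi=)`) to restore by noise
#'   rebalancing, or `NULL` to skip.
#' @param ppc_freqs frequencies for the entrainment ladder, Hz.
#' @return list of class `bl_ablation` with the manipulated network's
#'   spectrum, PPC ladder, burst-triggered FSI rate and rates.
#' @export
run_ablation <- function(network, ablate = "none", duration = 5000, seed = 1,
                         afferent_trains = NULL, noise_scale = NULL,
                         rebalance_to = NULL,
                         ppc_freqs = 2^seq(1, 8, by = 0.5)) {
  stopifnot(ablate %in% c("none", "fsi_pn", "pn_fsi", "fsi_fsi", "pn_pn"))
  net2 <- network
  if (ablate != "none") {
    net2$edges <- net2$edges[net2$edges$class != ablate, ]
    if (ablate == "fsi_fsi") net2$gaps <- NULL   # electrical synapses too
  }
  sc <- noise_scale
  if (!is.null(rebalance_to)) {
    rb <- rebalance_noise(net2, afferent_trains, rebalance_to,
                          start = if (is.null(sc)) list() else sc, seed = seed + 100)
    sc <- rb$scale
  }
  center <- matrix(rep(net2$box_um / 2, 3), 1)
  tr <- simulate_network(net2, duration, seed, afferent_trains = afferent_trains,
                         electrodes = center, noise_scale = sc)
  keep <- tr$t_ms > 1000
  lfp <- tr$lfp[keep, 1]
  spec <- welch_psd(lfp, 1000)
  sp <- tr$spikes[tr$spikes$t > 1000, ]
  types <- network$cells$type
  # PPC ladder per archetype (spikes pooled within type)
  ppc <- lapply(ppc_freqs, function(f0) {
    band <- c(f0 / 2^0.25, f0 * 2^0.25)
    if (band[2] >= 499) return(c(PN = NA_real_, FSI = NA_real_))
    bp <- band_phase(lfp, 1000, band, order = 2)
    ph_at <- function(cells) {
      idx <- round(sp$t[sp$cell %in% cells] - 1000)
      idx <- idx[idx >= 1 & idx <= length(lfp)]
      entrainment(bp$phase[idx])$ppc
    }
    c(PN = ph_at(which(types != "FSI")), FSI = ph_at(which(types == "FSI")))
  })
  ppc <- data.frame(freq = ppc_freqs, do.call(rbind, ppc))
  # PN-burst-triggered FSI rate
  nb <- sum(keep)
  rate_of <- function(cells) tabulate(pmin(pmax(round(sp$t[sp$cell %in% cells] - 1000), 1), nb), nbins = nb)
  rpn <- rate_of(which(types != "FSI")); rfsi <- rate_of(which(types == "FSI"))
  thr <- stats::quantile(rpn, 0.75)
  bursts <- which(rpn > thr)
  lags <- -100:100
  bta <- vapply(lags, function(l) {
    ix <- bursts + l; ix <- ix[ix >= 1 & ix <= nb]
    mean(rfsi[ix]) * 1000 / sum(types == "FSI")
  }, 0)
  structure(list(ablate = ablate, spectrum = spec, ppc = ppc,
                 burst_triggered = data.frame(lag_ms = lags, fsi_rate_hz = bta),
                 rates = population_rates(tr, network, from = 1000),
                 noise_scale = sc, lfp = lfp, traces = tr),
            class = "bl_ablation")
}

#' @export
print.bl_ablation <- function(x, ...) {
  gp <- gamma_peak_frequency(x$lfp)
  cat(sprintf("<bl_ablation %s> spectral peak %g Hz; rates: %s\n", x$ablate,
              gp$peak_hz,
              paste(sprintf("%s %.1f Hz", x$rates$type, x$rates$rate_hz), collapse = ", ")))
  invisible(x)
}

#' Two-ensemble competition experiment
#'
#' Assigns PNs to two groups (randomly, or as spheroids with given centers
#' and radius), gives each group its own afferents driven as homogeneous
#' Poisson processes, and measures per-group rates, pairwise spike
#' cross-correlations, entrainment of group spiking to the gamma phase of
#' the mean FSI EPSC, and group-to-FSI spike coherence.
#'
#' @param network a `bl_network` (typically the reduced 1,000-cell recipe).
#' @param rate1,rate2 afferent Poisson rates for groups 1 and 2, Hz.
#' @param mode `"random"` for random disjoint halves, `"spheroid"` for
#'   spatial spheroids.
#' @param centers 2 x 3 matrix of spheroid centers, um (spheroid mode).
#' @param radius_um spheroid radius (default approximately the mean gamma
#'   burst radius).
#' @param afferents_per_group afferent sources per group.
#' @param duration,seed run control (1-s settling period discarded).
#' @param noise_scale background scaling.
#' @param n_pairs pairs sampled per group for cross-correlations.
#' @return list of class `bl_competition`.
#' @export
run_competition <- function(network, rate1 = 20, rate2 = 5,
                            mode = c("random", "spheroid"),
                            centers = NULL, radius_um = 270,
                            afferents_per_group = NULL,
                            duration = 5000, seed = 1, noise_scale = NULL,
                            n_pairs = 100) {
  mode <- match.arg(mode)
  cells <- network$cells
  pn_ids <- which(cells$type != "FSI")
  if (mode == "random") {
    g1 <- withr_seed(seed, sample(pn_ids, floor(length(pn_ids) / 2)))
    g2 <- setdiff(pn_ids, g1)
  } else {
    if (is.null(centers)) stop("spheroid mode needs centers")
    d2c <- function(ctr) sqrt((cells$x - ctr[1])^2 + (cells$y - ctr[2])^2 + (cells$z - ctr[3])^2)
    g1 <- intersect(pn_ids, which(d2c(centers[1, ]) <= radius_um))
    g2 <- intersect(pn_ids, which(d2c(centers[2, ]) <= radius_um))
    g2 <- setdiff(g2, g1)
  }
  if (!length(g1) || !length(g2)) stop("empty PN group")
  n_aff <- afferents_per_group %||% max(10, round(network$n_afferents / 2))
  # group-specific afferents: each targets 40 PNs of its group
  av <- network$params$network$afferents
  mk_aff <- function(grp, offset, sd) {
    withr_seed(sd, {
      do.call(rbind, lapply(seq_len(n_aff), function(a) {
        tgt <- sample(grp, min(av$targets_per_afferent, length(grp)))
        data.frame(aff = a + offset, dst = tgt, class = "aff_pn",
                   w1 = draw_weights(length(tgt), network$params$synapses$classes$aff_pn$ampa$strength, network$params),
                   w2 = draw_weights(length(tgt), network$params$synapses$classes$aff_pn$nmda$strength, network$params),
                   delay_ms = conduction_delay(rep(0, length(tgt)), network$params))
      }))
    })
  }
  net2 <- network
  net2$afferents <- rbind(mk_aff(g1, 0, seed + 11), mk_aff(g2, n_aff, seed + 12))
  net2$n_afferents <- 2L * n_aff
  trains <- c(poisson_trains(rate1, duration, n_aff, seed + 13),
              poisson_trains(rate2, duration, n_aff, seed + 14))
  fsi_ids <- which(cells$type == "FSI")
  tr <- simulate_network(net2, duration, seed, afferent_trains = trains,
                         vc_cells = fsi_ids, noise_scale = noise_scale)
  sp <- tr$spikes[tr$spikes$t > 1000, ]
  dur_s <- (duration - 1000) / 1000
  rate_g <- function(g) sum(sp$cell %in% g) / length(g) / dur_s
  # mean FSI EPSC, gamma phase
  mean_epsc <- rowMeans(tr$epsc)[tr$t_ms > 1000]
  bp <- band_phase(mean_epsc, 1000, c(60, 80), order = 2)
  ent_g <- function(g) {
    idx <- round(sp$t[sp$cell %in% g] - 1000)
    idx <- idx[idx >= 1 & idx <= length(mean_epsc)]
    entrainment(bp$phase[idx])
  }
  # pairwise gamma-band cross-correlation strength within groups
  xc_g <- function(g, sd) {
    withr_seed(sd, {
      active <- intersect(g, unique(sp$cell))
      if (length(active) < 4) return(numeric(0))
      vapply(seq_len(n_pairs), function(i) {
        pq <- sample(active, 2)
        a <- sp$t[sp$cell == pq[1]]; b <- sp$t[sp$cell == pq[2]]
        if (length(a) < 3 || length(b) < 3) return(NA_real_)
        sc <- spike_coherence(a - 1000, b - 1000, duration - 1000, max_lag_ms = 64)
        gam <- sc$freq >= 50 & sc$freq <= 80
        mean(Mod(sc$coherence[gam]))
      }, 0)
    })
  }
  # group-to-FSI-population coherence
  fsi_spk <- sp$t[sp$cell %in% fsi_ids] - 1000
  coh_g <- function(g) {
    pn_spk <- sp$t[sp$cell %in% g] - 1000
    if (length(pn_spk) < 10 || length(fsi_spk) < 10) return(NULL)
    spike_coherence(pn_spk, fsi_spk, duration - 1000, max_lag_ms = 128)
  }
  structure(list(
    groups = list(g1 = g1, g2 = g2), rates = c(g1 = rate_g(g1), g2 = rate_g(g2)),
    drive = c(rate1 = rate1, rate2 = rate2), mode = mode,
    entrainment = list(g1 = ent_g(g1), g2 = ent_g(g2)),
    xcorr_gamma = list(g1 = xc_g(g1, seed + 21), g2 = xc_g(g2, seed + 22)),
    fsi_coherence = list(g1 = coh_g(g1), g2 = coh_g(g2)),
    traces = tr), class = "bl_competition")
}

#' @export
print.bl_competition <- function(x, ...) {
  cat(sprintf("<bl_competition %s> drive %g/%g Hz -> rates %.2f/%.2f Hz; RV %.3f/%.3f\n",
              x$mode, x$drive[1], x$drive[2], x$rates[1], x$rates[2],
              x$entrainment$g1$rv, x$entrainment$g2$rv))
  invisible(x)
}

#' Gamma-cycle-aligned synaptic currents, split by spiking
#'
#' Aligns EPSC/IPSC traces to the phase of gamma cycles of the local field
#' and averages separately over cycles that did or did not contain a spike
#' of the cell; also returns the spike-minus-no-spike difference curves.
#'
#' @param epsc,ipsc synaptic current series, 1 kHz (nA).
#' @param lfp field series used to define gamma cycles, 1 kHz.
#' @param spike_t spike times, ms (same clock as the series).
#' @param band gamma band, Hz.
#' @param n_bins phase bins per cycle.
#' @return list of class `bl_cycle_psc` with per-phase-bin means for
#'   spike/no-spike cycles and their differences; warns below 50 cycles.
#' @export
phase_conditioned_psc <- function(epsc, ipsc, lfp, spike_t, band = c(60, 80),
                                  n_bins = 18) {
  bp <- band_phase(lfp, 1000, band, order = 2)
  ph <- bp$phase
  # cycle boundaries at upward -pi crossings (phase wraps)
  wrap <- which(diff(ph) < -pi)
  if (length(wrap) < 3) stop("too few gamma cycles in the field series")
  n_cyc <- length(wrap) - 1
  if (n_cyc < 50) warning("only ", n_cyc, " gamma cycles; averages will be noisy")
  spk_bin <- unique(pmax(1, round(spike_t)))
  bins <- cut(ph, seq(-pi, pi, length.out = n_bins + 1), include.lowest = TRUE)
  acc <- array(0, c(n_bins, 2, 2))  # bin x (epsc, ipsc) x (spike, no-spike)
  cnt <- matrix(0, n_bins, 2)
  for (ci in seq_len(n_cyc)) {
    ix <- (wrap[ci] + 1):wrap[ci + 1]
    has_spike <- any(spk_bin %in% ix)
    col <- if (has_spike) 1 else 2
    b <- as.integer(bins[ix])
    for (j in seq_along(ix)) {
      acc[b[j], 1, col] <- acc[b[j], 1, col] + epsc[ix[j]]
      acc[b[j], 2, col] <- acc[b[j], 2, col] + ipsc[ix[j]]
    }
    cnt[, col] <- cnt[, col] + tabulate(b, n_bins)
  }
  phase_mid <- seq(-pi, pi, length.out = n_bins + 1)[-1] - pi / n_bins
  mean_or_na <- function(k, col) ifelse(cnt[, col] > 0, acc[, k, col] / cnt[, col], NA)
  out <- data.frame(phase = phase_mid,
                    epsc_spike = mean_or_na(1, 1), epsc_nospike = mean_or_na(1, 2),
                    ipsc_spike = mean_or_na(2, 1), ipsc_nospike = mean_or_na(2, 2))
  out$epsc_diff <- out$epsc_spike - out$epsc_nospike
  out$ipsc_diff <- out$ipsc_spike - out$ipsc_nospike
  structure(list(curves = out, n_cycles = n_cyc), class = "bl_cycle_psc")
}

#' Spike probability versus EPSC strength by gamma phase
#'
#' Divides gamma cycles into phase quadrants; within each quadrant the EPSC
#' strength is binned into deciles and the probability of spiking is
#' measured per bin.
#'
#' @param epsc EPSC series, 1 kHz (nA; magnitudes are used).
#' @param lfp field series defining the gamma phase, 1 kHz.
#' @param spike_t spike times, ms.
#' @param band gamma band, Hz.
#' @param n_quadrants number of phase divisions.
#' @param n_strength strength bins (deciles by default).
#' @return data.frame `quadrant`, `strength_bin`, `strength`,
#'   `p_spike`, `n`; empty strength bins are merged into their neighbor
#'   with a warning.
#' @export
epsc_sensitivity_by_phase <- function(epsc, lfp, spike_t, band = c(60, 80),
                                      n_quadrants = 4, n_strength = 10) {
  bp <- band_phase(lfp, 1000, band, order = 2)
  quad <- cut(bp$phase, seq(-pi, pi, length.out = n_quadrants + 1),
              include.lowest = TRUE, labels = FALSE)
  spk <- rep(FALSE, length(epsc))
  sb <- round(spike_t); sb <- sb[sb >= 1 & sb <= length(epsc)]
  spk[sb] <- TRUE
  s <- abs(epsc)
  out <- list()
  for (q in seq_len(n_quadrants)) {
    ix <- which(quad == q)
    if (!length(ix)) next
    br <- unique(stats::quantile(s[ix], probs = seq(0, 1, length.out = n_strength + 1)))
    if (length(br) < n_strength + 1)
      warning("tied strength deciles in quadrant ", q, "; bins merged")
    bin <- cut(s[ix], br, include.lowest = TRUE, labels = FALSE)
    for (b in seq_len(max(bin))) {
      jj <- ix[bin == b]
      out[[length(out) + 1]] <- data.frame(
        quadrant = q, strength_bin = b, strength = mean(s[jj]),
        p_spike = mean(spk[jj]), n = length(jj))
    }
  }
  do.call(rbind, out)
}

#' Deterministic fixture bundles
#'
#' Small inputs exercising every module: a reciprocally connected PN-FSI
#' pair with the published synapse parameters, a 50-cell network, the
#' reduced 1,000-cell recipe, and a synthetic electrode-grid gamma series
#' with translating amplitude blobs and known ground truth.
#'
#' @param kind fixture name.
#' @param seed seed.
#' @param params model parameters.
#' @return the fixture (network, or list with data and ground truth).
#' @export
make_fixtures <- function(kind = c("two_cell_motif", "fifty_cell_net",
                                   "reduced_bl_1000", "synthetic_lfp_grid"),
                          seed = 1, params = bl_params()) {
  kind <- match.arg(kind)
  switch(kind,
    two_cell_motif = {
      cells <- data.frame(type = c("PN_A", "FSI"), x = c(0, 100), y = 0, z = 0)
      edges <- data.frame(src = c(1, 2), dst = c(2, 1),
                          class = c("pn_fsi", "fsi_pn"),
                          w1 = c(7, 12), w2 = c(7, 0), delay_ms = c(0.95, 0.95))
      motif_network(cells, edges, params = params)
    },
    fifty_cell_net = {
      rec <- bl_recipe(scale = 50 / 27000, params = params)
      build_network(rec, seed)
    },
    reduced_bl_1000 = build_network(reduced_recipe(1000, params), seed),
    synthetic_lfp_grid = synthetic_gamma_grid(seed = seed)
  )
}

#' Synthetic electrode-grid gamma series with known bursts
#'
#' Gaussian-envelope 70-Hz bursts (optionally translating across the grid)
#' added to spatially independent noise; the generator records the ground
#' truth used by the detector tests.
#'
#' @param n grid side (n x n x n electrodes).
#' @param duration_ms series length.
#' @param spacing_um electrode spacing.
#' @param bursts data.frame with columns `t0` (center time, ms), `x0`,
#'   `y0`, `z0` (center, grid units), `vx` (grid units/ms along x),
#'   `amp` (peak Z), `sigma_t` (ms), `sigma_s` (grid units).
#' @param noise_sd baseline envelope noise SD.
#' @param seed seed.
#' @return list with `z` (4-D array of Z-scored gamma amplitude), `phi`
#'   (raw series matrix, time x electrode), `truth`, `dims`.
#' @export
synthetic_gamma_grid <- function(n = 7, duration_ms = 1500, spacing_um = 125,
                                 bursts = data.frame(t0 = 700, x0 = 2, y0 = 4,
                                                     z0 = 4, vx = 0.02,
                                                     amp = 4, sigma_t = 50,
                                                     sigma_s = 1.2),
                                 noise_sd = 0.15, seed = 1) {
  withr_seed(seed, {
    tt <- seq_len(duration_ms)
    env <- array(stats::rnorm(n^3 * duration_ms), c(n, n, n, duration_ms))
    # envelope fields are smooth in space and time; separable moving
    # averages shape the noise accordingly before rescaling to noise_sd
    sm <- function(x, k) stats::filter(x, rep(1 / k, k), circular = TRUE)
    for (ix in 1:n) for (iy in 1:n) for (iz in 1:n)
      env[ix, iy, iz, ] <- as.numeric(sm(env[ix, iy, iz, ], 25))
    for (d in 1:3) {
      env <- aperm(apply(env, setdiff(1:4, d), function(x) as.numeric(sm(x, 3))),
                   append(2:4, 1, after = d - 1))
    }
    env <- env * (noise_sd / stats::sd(env))
    env[env < 0] <- 0
    for (bi in seq_len(nrow(bursts))) {
      b <- bursts[bi, ]
      gt <- exp(-(tt - b$t0)^2 / (2 * b$sigma_t^2))
      cx <- b$x0 + b$vx * (tt - b$t0)
      for (ix in 1:n) for (iy in 1:n) for (iz in 1:n) {
        gs <- exp(-((ix - cx)^2 + (iy - b$y0)^2 + (iz - b$z0)^2) / (2 * b$sigma_s^2))
        env[ix, iy, iz, ] <- env[ix, iy, iz, ] + b$amp * gt * gs
      }
    }
    phi <- matrix(0, duration_ms, n^3)
    carrier <- sin(2 * pi * 70 * tt / 1000)
    k <- 1
    for (iz in 1:n) for (iy in 1:n) for (ix in 1:n) {
      phi[, k] <- env[ix, iy, iz, ] * carrier
      k <- k + 1
    }
    list(z = env, phi = phi, truth = bursts, dims = c(n, n, n),
         spacing_um = spacing_um)
  })
}
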