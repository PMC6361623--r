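#' Welch power spectral density
#'
#' Hamming-windowed segment-averaged periodogram (500-ms windows advanced
#' by 250 ms by default), one-sided.
#'
#' @param x numeric series.
#' @param fs sampling rate, Hz.
#' @param window_s,step_s segment length and step, seconds.
#' @return data.frame with `freq` (Hz) and `power`.
#' @export
welch_psd <- function(x, fs, window_s = 0.5, step_s = 0.25) {
  nw <- round(window_s * fs); nstep <- round(step_s * fs)
  if (length(x) < nw) stop("series shorter than one window")
  w <- 0.54 - 0.46 * cos(2 * pi * seq_len(nw) / (nw + 1))
  starts <- seq(1, length(x) - nw + 1, by = nstep)
  acc <- numeric(nw %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + nw - 1)]
    seg <- (seg - mean(seg)) * w
    ft <- stats::fft(seg)
    p <- Mod(ft[seq_len(nw %/% 2 + 1)])^2
    acc <- acc + p
  }
  scale <- 1 / (fs * sum(w^2))
  p <- acc / length(starts) * scale
  p[2:(length(p) - 1)] <- 2 * p[2:(length(p) - 1)]
  data.frame(freq = (seq_len(nw %/% 2 + 1) - 1) * fs / nw, power = p)
}

#' Fit a 1/f^a power law to a spectrum
#'
#' Log-log least squares over `fit_range`, optionally excluding a band
#' (e.g. the gamma bump) from the fit.
#'
#' @param freq,power spectrum.
#' @param fit_range frequencies used for the fit, Hz.
#' @param exclude band to exclude from the fit, Hz (or `NULL`).
#' @return list with `a`, `alpha` (power ~ a * f^-alpha).
#' @export
fit_power_law <- function(freq, power, fit_range = c(2, 200), exclude = NULL) {
  use <- freq >= fit_range[1] & freq <= fit_range[2] & power > 0
  if (!is.null(exclude)) use <- use & !(freq >= exclude[1] & freq <= exclude[2])
  if (sum(use) < 3) return(list(a = NA_real_, alpha = NA_real_))
  fit <- stats::lm(log(power[use]) ~ log(freq[use]))
  list(a = exp(stats::coef(fit)[[1]]), alpha = -stats::coef(fit)[[2]])
}

#' Gamma peak frequency of an LFP spectrum
#'
#' Welch spectrum, removal of a 1/f^a power-law fit (fitted with the
#' search band excluded), and the frequency of the maximal residual within
#' the search band.
#'
#' At reduced network scale a period-doubling subharmonic can accompany
#' the PING fundamental (two bumps, one near half the other).  When the
#' tallest residual peak has a companion near twice its frequency whose
#' residual exceeds `harmonic_ratio` times its own, the companion (the
#' cycle fundamental) is reported; set `harmonic_ratio = Inf` to disable.
#'
#' @param x LFP series.
#' @param fs sampling rate, Hz.
#' @param search band searched for the bump, Hz.
#' @param harmonic_ratio subharmonic disambiguation threshold.
#' @return list with `peak_hz`, the residual spectrum, and the fit.
#' @export
gamma_peak_frequency <- function(x, fs = 1000, search = c(30, 100),
                                 harmonic_ratio = 0.4) {
  ps <- welch_psd(x, fs)
  fit <- fit_power_law(ps$freq, ps$power, fit_range = c(2, 200), exclude = search)
  inb <- which(ps$freq >= search[1] & ps$freq <= search[2] & ps$power > 0)
  resid <- log(ps$power[inb]) - log(fit$a * ps$freq[inb]^(-fit$alpha))
  f_in <- ps$freq[inb]
  top_i <- which.max(resid)
  peak <- f_in[top_i]
  comp <- which(f_in >= 1.6 * peak & f_in <= 2.4 * peak)
  if (length(comp)) {
    ci <- comp[which.max(resid[comp])]
    if (resid[ci] > harmonic_ratio * resid[top_i]) peak <- f_in[ci]
  }
  list(peak_hz = peak, residual = data.frame(freq = f_in, resid = resid),
       spectrum = ps, fit = fit)
}

#' Morlet wavelet spectrogram
#'
#' Complex Morlet decomposition from 1 to 256 Hz in quarter-octave steps
#' (seven-cycle wavelets): amplitude is the modulus and phase the angle of
#' the complex coefficients.
#'
#' @param x numeric series.
#' @param fs sampling rate, Hz.
#' @param freqs analysis frequencies, Hz (default quarter octaves 1-256).
#' @param n_cycles wavelet width in cycles.
#' @return list with `t` (s), `freq`, `amplitude` and `phase` matrices
#'   (time x frequency).
#' @export
morlet_spectrogram <- function(x, fs, freqs = 2^seq(0, 8, by = 0.25),
                               n_cycles = 7) {
  n <- length(x)
  nfft <- stats::nextn(2 * n, 2)
  fx <- stats::fft(c(x - mean(x), rep(0, nfft - n)))
  fgrid <- (seq_len(nfft) - 1) / nfft * fs
  fgrid[fgrid > fs / 2] <- fgrid[fgrid > fs / 2] - fs
  amp <- matrix(0, n, length(freqs)); ph <- matrix(0, n, length(freqs))
  for (k in seq_along(freqs)) {
    f0 <- freqs[k]
    sigma_f <- f0 / n_cycles          # spectral width of a 7-cycle wavelet
    wl <- exp(-(fgrid - f0)^2 / (2 * sigma_f^2)) * 2
    co <- stats::fft(fx * wl, inverse = TRUE)[seq_len(n)] / nfft
    amp[, k] <- Mod(co); ph[, k] <- Arg(co)
  }
  list(t = (seq_len(n) - 1) / fs, freq = freqs, amplitude = amp, phase = ph)
}

#' Analytic signal via the Hilbert transform
#'
#' @param x numeric series.
#' @return complex analytic signal (same length).
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  h <- rep(0, n)
  if (n %% 2 == 0) { h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 }
  else { h[1] <- 1; h[2:((n + 1) / 2)] <- 2 }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Band phase and amplitude of an LFP
#'
#' Zero-phase Butterworth bandpass (forward-backward filtering) followed by
#' the Hilbert transform.
#'
#' @param x LFP series.
#' @param fs sampling rate, Hz (must exceed twice the band top).
#' @param band passband, Hz.
#' @param order filter order (2 for entrainment analyses, 4 for burst
#'   detection).
#' @return list with `filtered`, `phase` (radians) and `amplitude`.
#' @export
band_phase <- function(x, fs, band = c(60, 80), order = 2) {
  if (band[2] >= fs / 2) stop("band top must be below the Nyquist frequency")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bf, x)
  a <- analytic_signal(xf)
  list(filtered = xf, phase = Arg(a), amplitude = Mod(a))
}

#' Detect gamma bursts on a single electrode
#'
#' The 60-80-Hz envelope (order-4 zero-phase Butterworth + Hilbert) is
#' thresholded at its mean + 2 SD; each suprathreshold excursion is one
#' event whose duration is the span where the envelope exceeds 25% of the
#' event peak.
#'
#' @param x LFP series (>= 10 s recommended for stable mean/SD).
#' @param fs sampling rate, Hz.
#' @param band gamma band, Hz.
#' @param z_thresh detection threshold in SDs above the mean.
#' @param border_frac border criterion as a fraction of the event peak.
#' @return data.frame with `onset`, `offset`, `peak_t` (ms), `peak_amp`,
#'   `peak_z`, `duration` (ms).
#' @export
detect_bursts <- function(x, fs = 1000, band = c(60, 80), z_thresh = 2,
                          border_frac = 0.25) {
  bp <- band_phase(x, fs, band, order = 4)
  env <- bp$amplitude
  mu <- mean(env); sdv <- stats::sd(env)
  thr <- mu + z_thresh * sdv
  # guard against a degenerate (numerically constant) envelope, whose
  # sub-ppm ripple would otherwise sit exactly at the threshold
  above <- env > thr + 1e-4 * mu
  if (!any(above)) {
    return(data.frame(onset = numeric(0), offset = numeric(0),
                      peak_t = numeric(0), peak_amp = numeric(0),
                      peak_z = numeric(0), duration = numeric(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  seg <- which(r$values)
  out <- lapply(seg, function(si) {
    i0 <- starts[si]; i1 <- ends[si]
    ipk <- i0 - 1 + which.max(env[i0:i1])
    lev <- border_frac * env[ipk]
    a <- ipk; while (a > 1 && env[a - 1] > lev) a <- a - 1
    b <- ipk; while (b < length(env) && env[b + 1] > lev) b <- b + 1
    data.frame(onset = a, offset = b, peak_t = ipk, peak_amp = env[ipk],
               peak_z = (env[ipk] - mu) / sdv, duration = (b - a + 1))
  })
  out <- do.call(rbind, out)
  ms <- 1000 / fs
  out$onset <- out$onset * ms; out$offset <- out$offset * ms
  out$peak_t <- out$peak_t * ms; out$duration <- out$duration * ms
  out
}

#' Watershed segmentation of a mid-gamma power series
#'
#' Discretizes the power series (bins of half the mean absolute change in
#' power between successive gamma cycles), splits it into watershed
#' segments at local minima of the discretized series, and tabulates each
#' burst's peak-power percentile (5-percentile bins) against its duration
#' (5-ms bins).
#'
#' @param power mid-gamma power series (e.g. the 64-Hz wavelet amplitude
#'   squared), 1 kHz.
#' @param fs sampling rate, Hz.
#' @param cycle_hz the carrier frequency defining "one cycle" for the
#'   discretization rule.
#' @return list with `bursts` (per-segment peak, percentile, duration) and
#'   `map` (joint histogram, percentile bin x duration bin).
#' @export
burst_amplitude_duration_map <- function(power, fs = 1000, cycle_hz = 64) {
  cyc <- max(1L, round(fs / cycle_hz))
  binw <- mean(abs(diff(power[seq(1, length(power), by = cyc)]))) / 2
  if (!is.finite(binw) || binw <= 0) binw <- stats::sd(power) / 10
  q <- floor(power / binw)
  # segment boundaries: local minima of the discretized series (plateaus
  # collapse to their run)
  r <- rle(q)
  nr <- length(r$values)
  if (nr < 3) {
    seg_id <- rep(1L, length(q))
  } else {
    vals <- r$values
    is_min <- c(FALSE, vals[2:(nr - 1)] < vals[1:(nr - 2)] &
                       vals[2:(nr - 1)] < vals[3:nr], FALSE)
    bnd <- cumsum(r$lengths)[is_min]           # split after each minimum run
    seg_id <- findInterval(seq_along(q) - 1, c(0, bnd)) + 0L
    seg_id <- seg_id - min(seg_id) + 1L
  }
  ms <- 1000 / fs
  bursts <- do.call(rbind, lapply(split(seq_along(q), seg_id), function(ix) {
    data.frame(peak = max(power[ix]), duration = length(ix) * ms)
  }))
  bursts$percentile <- 100 * rank(bursts$peak) / nrow(bursts)
  pb <- cut(bursts$percentile, seq(0, 100, 5), include.lowest = TRUE)
  db <- cut(pmin(bursts$duration, 499.9), seq(0, 500, 5), include.lowest = TRUE)
  list(bursts = bursts, map = table(pb, db))
}

#' Spatiotemporal gamma bursts on an electrode grid (4-D watershed)
#'
#' Z-scored (optionally edge-corrected) gamma envelopes on a 3-D electrode
#' grid are discretized into amplitude bins and segmented into contiguous
#' basins by a 4-D watershed (6-neighborhood in space, adjacency in time;
#' flooding in decreasing amplitude order, ties to the steepest
#' already-claimed neighbor).  Basins whose peak exceeds `peak_thresh`
#' Z-scores are events; members below `border_frac` of the peak are
#' trimmed.
#'
#' @param z 4-D array (nx, ny, nz, time) of Z-scored gamma amplitude.
#' @param spacing_um electrode spacing, um.
#' @param dt_ms time step of the envelope series, ms.
#' @param peak_thresh minimum peak amplitude (Z) for a burst.
#' @param border_frac border criterion, fraction of the peak.
#' @param bin amplitude discretization bin (Z units).
#' @param phase optional 4-D array of instantaneous gamma phase on the same
#'   grid; per burst, the bias-corrected PLV across the 3 x 3 x 3 electrode
#'   neighborhood of the peak site over the burst duration is reported.
#' @return list with `bursts` (peak Z, duration ms, volume in sites, path
#'   length um, net displacement um, speed um/ms, peak location/time, and
#'   `plv` when `phase` is given) and `members` (per-burst data.frame of
#'   member voxels).
#' @export
detect_bursts_4d <- function(z, spacing_um = 125, dt_ms = 1, peak_thresh = 2,
                             border_frac = 0.25, bin = 0.1, phase = NULL) {
  dm <- dim(z)
  if (length(dm) != 4) stop("z must be a 4-D array (x, y, z, time)")
  q <- floor(z / bin)
  lab <- integer(length(z))
  dm4 <- dim(z)
  nx <- dm4[1]; ny <- dm4[2]; nz <- dm4[3]; nt <- dm4[4]
  nbr_off <- c(-1L, 1L, -nx, nx, -nx * ny, nx * ny, -nx * ny * nz, nx * ny * nz)
  # neighbor list respecting the box (6-neighborhood in space + time)
  sxy <- nx * ny; sxyz <- sxy * nz
  neighbors_of <- function(v) {
    v0 <- v - 1L
    i1 <- v0 %% nx; i2 <- (v0 %/% nx) %% ny
    i3 <- (v0 %/% sxy) %% nz; i4 <- v0 %/% sxyz
    out <- integer(0)
    if (i1 > 0L) out <- c(out, v - 1L)
    if (i1 < nx - 1L) out <- c(out, v + 1L)
    if (i2 > 0L) out <- c(out, v - nx)
    if (i2 < ny - 1L) out <- c(out, v + nx)
    if (i3 > 0L) out <- c(out, v - sxy)
    if (i3 < nz - 1L) out <- c(out, v + sxy)
    if (i4 > 0L) out <- c(out, v - sxyz)
    if (i4 < nt - 1L) out <- c(out, v + sxyz)
    out
  }
  active_vox <- which(q > 0)
  lev_of <- q[active_vox]
  inlev <- logical(length(z))
  peaks <- numeric(0)
  # flood by descending discretized level; within a level, first grow
  # existing basins into the level (plateau-aware BFS), then seed new
  # basins from the remaining connected components
  for (L in sort(unique(lev_of), decreasing = TRUE)) {
    vox <- active_vox[lev_of == L]
    inlev[vox] <- TRUE
    queue <- integer(0)
    for (v in vox) {
      nb <- neighbors_of(v)
      lb <- lab[nb]
      if (any(lb > 0L)) {
        lab[v] <- lb[lb > 0L][which.max(q[nb[lb > 0L]])]
        queue <- c(queue, v)
      }
    }
    qi <- 1L
    while (qi <= length(queue)) {
      v <- queue[qi]; qi <- qi + 1L
      for (w in neighbors_of(v)) {
        if (lab[w] == 0L && inlev[w]) {
          lab[w] <- lab[v]
          queue <- c(queue, w)
        }
      }
    }
    # remaining voxels of this level: new basin per connected component
    rest <- vox[lab[vox] == 0L]
    while (length(rest)) {
      seedv <- rest[1]
      peaks <- c(peaks, 0)
      b <- length(peaks)
      comp <- seedv; lab[seedv] <- b
      ci2 <- 1L
      while (ci2 <= length(comp)) {
        v <- comp[ci2]; ci2 <- ci2 + 1L
        for (w in neighbors_of(v)) {
          if (lab[w] == 0L && inlev[w]) { lab[w] <- b; comp <- c(comp, w) }
        }
      }
      peaks[b] <- max(z[comp])
      rest <- rest[lab[rest] == 0L]
    }
    inlev[vox] <- FALSE
  }
  keep <- which(peaks > peak_thresh)
  bursts <- list(); members <- list()
  for (bi in seq_along(keep)) {
    b <- keep[bi]
    vox <- which(lab == b)
    vox <- vox[z[vox] >= border_frac * peaks[b]]
    if (!length(vox)) next
    ci <- arrayInd(vox, dm)
    zt <- z[vox]
    sites <- unique(ci[, 1:3, drop = FALSE])
    tsteps <- sort(unique(ci[, 4]))
    # center trajectory: mean member coordinate per time step
    traj <- t(vapply(tsteps, function(tt) {
      colMeans(ci[ci[, 4] == tt, 1:3, drop = FALSE]) * spacing_um
    }, numeric(3)))
    path <- if (nrow(traj) > 1) sum(sqrt(rowSums(diff(traj)^2))) else 0
    net_disp <- if (nrow(traj) > 1)
      sqrt(sum((traj[nrow(traj), ] - traj[1, ])^2)) else 0
    dur <- length(tsteps) * dt_ms
    ipk <- vox[which.max(zt)]
    pkc <- arrayInd(ipk, dm)
    plv <- NA_real_
    if (!is.null(phase)) {
      xr <- max(1, pkc[1] - 1):min(dm[1], pkc[1] + 1)
      yr <- max(1, pkc[2] - 1):min(dm[2], pkc[2] + 1)
      zr <- max(1, pkc[3] - 1):min(dm[3], pkc[3] + 1)
      ph <- matrix(aperm(phase[xr, yr, zr, tsteps, drop = FALSE], c(4, 1, 2, 3)),
                   nrow = length(tsteps))
      plv <- plv_unbiased(ph)
    }
    bursts[[bi]] <- data.frame(
      peak_z = peaks[b], duration = dur, volume = nrow(sites),
      path_um = path, net_displacement_um = net_disp, speed = path / dur,
      plv = plv,
      peak_x = pkc[1], peak_y = pkc[2], peak_z_idx = pkc[3], peak_t = pkc[4])
    members[[bi]] <- data.frame(x = ci[, 1], y = ci[, 2], z = ci[, 3],
                                t = ci[, 4], amp = zt)
  }
  list(bursts = if (length(bursts)) do.call(rbind, bursts) else
         data.frame(peak_z = numeric(0), duration = numeric(0),
                    volume = numeric(0), path_um = numeric(0), speed = numeric(0)),
       members = members)
}

#' Spike-field entrainment
#'
#' Resultant vector length (RV), preferred phase, and the pairwise phase
#' consistency (PPC), an estimator whose expectation does not depend on the
#' spike count: `PPC = (n^2 RV^2 - n) / (n (n - 1))`, the average cosine of
#' all pairwise phase differences.
#'
#' @param phases spike phases, radians.
#' @param min_rv minimum spike count for the RV (returns `NA` below it).
#' @return list with `rv`, `mean_phase`, `ppc`, `n`.
#' @export
entrainment <- function(phases, min_rv = 10) {
  n <- length(phases)
  if (n < 2) return(list(rv = NA_real_, mean_phase = NA_real_, ppc = NA_real_, n = n))
  m <- mean(exp(1i * phases))
  rv <- Mod(m)
  ppc <- (n^2 * rv^2 - n) / (n * (n - 1))
  list(rv = if (n >= min_rv) rv else NA_real_,
       mean_phase = Arg(m), ppc = ppc, n = n)
}

#' Bias-corrected pairwise phase-locking value across channels
#'
#' For each channel pair the squared phase-locking value of the phase
#' difference over time is debiased with the n-dependent correction
#' `(n PLV^2 - 1) / (n - 1)`; the result is the square root of the mean
#' corrected value over all pairs (floored at zero).
#'
#' @param phases matrix (time x channels) of instantaneous phases.
#' @return scalar unbiased PLV estimate.
#' @export
plv_unbiased <- function(phases) {
  nc <- ncol(phases); n <- nrow(phases)
  if (nc < 2 || n < 2) return(NA_real_)
  acc <- 0; np <- 0
  for (a in 1:(nc - 1)) for (b in (a + 1):nc) {
    plv2 <- Mod(mean(exp(1i * (phases[, a] - phases[, b]))))^2
    acc <- acc + (n * plv2 - 1) / (n - 1)
    np <- np + 1
  }
  sqrt(max(0, acc / np))
}

#' Spike-train coherence and autocorrelation-corrected cross-correlation
#'
#' Cross- and auto-correlations of 1-ms binned trains over a +-`max_lag`
#' window are transformed to the frequency domain;
#' `coherence = XCorr / sqrt(ACorr_a * ACorr_b)`, and the inverse
#' transform of the coherence gives the cross-correlation with the
#' periodicities of the autocorrelations factored out.
#'
#' @param a,b spike-time vectors (ms).
#' @param duration_ms common duration.
#' @param max_lag_ms correlation window half-width, ms.
#' @return list with `freq` (Hz), `coherence` (complex), `lags` (ms),
#'   `corrected` (real), or `NULL` elements if a train is empty.
#' @export
spike_coherence <- function(a, b, duration_ms, max_lag_ms = 128) {
  if (!length(a) || !length(b))
    return(list(freq = NULL, coherence = NULL, lags = NULL, corrected = NULL))
  nb <- ceiling(duration_ms)
  xa <- tabulate(pmin(floor(a) + 1, nb), nbins = nb)
  xb <- tabulate(pmin(floor(b) + 1, nb), nbins = nb)
  xa <- xa - mean(xa); xb <- xb - mean(xb)
  L <- max_lag_ms
  cc <- function(u, v) {   # sum_t u[t] v[t+lag] for lag in -L..L
    nfft <- stats::nextn(nb + L, 2)
    fu <- stats::fft(c(u, rep(0, nfft - nb)))
    fv <- stats::fft(c(v, rep(0, nfft - nb)))
    r <- Re(stats::fft(Conj(fu) * fv, inverse = TRUE)) / nfft
    c(r[(nfft - L + 1):nfft], r[1:(L + 1)])
  }
  xab <- cc(xa, xb); xaa <- cc(xa, xa); xbb <- cc(xb, xb)
  n <- length(xab)        # 2L + 1, index i <-> lag i - L - 1
  # Bartlett lag window (guarantees nonnegative auto-spectra), then rotate
  # to circular order (lag 0 first) before transforming
  taper <- 1 - abs(-L:L) / (L + 1)
  wrap <- function(r) { r <- r * taper; c(r[(L + 1):n], r[1:L]) }
  Fab <- stats::fft(wrap(xab))
  Faa <- Re(stats::fft(wrap(xaa))); Fbb <- Re(stats::fft(wrap(xbb)))
  den <- sqrt(pmax(Faa, 0) * pmax(Fbb, 0))
  coh <- Fab / ifelse(den > 1e-12 * max(den), den, Inf)
  corr_w <- Re(stats::fft(coh, inverse = TRUE)) / n
  lags_w <- c(0:L, -(L:1))
  o <- order(lags_w)
  freq <- (seq_len(n) - 1) / n * 1000
  list(freq = freq[seq_len(L + 1)], coherence = coh[seq_len(L + 1)],
       lags = lags_w[o], corrected = corr_w[o])
}
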