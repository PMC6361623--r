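#' Line-source extracellular potential
#'
#' Potential at an electrode from a cylindrical segment carrying a uniform
#' transmembrane current, in a homogeneous resistive medium:
#' `phi = I / (4 pi sigma ds) * log| (sqrt(h^2+r^2) - h) / (sqrt(l^2+r^2) - l) |`
#' with `r` the radial distance from the segment axis, `h` the longitudinal
#' distance from the far end of the segment and `l = ds + h` the distance
#' from its near end.
#'
#' @param a,b segment endpoints, um (matrices, one row per segment, or
#'   length-3 vectors).
#' @param electrode electrode position, um (length-3).
#' @param i_nA per-segment current, nA (positive outward).
#' @param sigma extracellular conductivity, S/m.
#' @param guard minimum radial distance, um; electrodes closer to the axis
#'   than this are evaluated at the guard distance (the expression is
#'   singular on the axis).
#' @return potential in mV (sum over segments if `i_nA` has length > 1).
#' @export
line_source_potential <- function(a, b, electrode, i_nA, sigma = 0.3, guard = 1) {
  co <- line_source_coef(a, b, electrode, sigma, guard)
  sum(co * i_nA)
}

# per-segment coefficient, mV per nA
line_source_coef <- function(a, b, electrode, sigma = 0.3, guard = 1) {
  a <- matrix(a, ncol = 3); b <- matrix(b, ncol = 3)
  d <- b - a
  ds <- sqrt(rowSums(d^2))
  u <- d / ds
  eb <- matrix(electrode, nrow(a), 3, byrow = TRUE) - b
  h <- rowSums(eb * u)
  perp <- eb - h * u
  r <- pmax(sqrt(rowSums(perp^2)), guard)
  l <- ds + h
  num <- abs(sqrt(h^2 + r^2) - h)
  den <- abs(sqrt(l^2 + r^2) - l)
  log(num / den) / (4 * pi * sigma * ds)
}

# Segment geometry for every compartment of every cell: the soma is a short
# line along the cell's dendrite axis; dendrites extend from the soma ends
# along +axis (apical / FSI dendrite) and -axis (the passive-matching
# dendrite).
comp_segments <- function(network) {
  params <- network$params
  cells <- network$cells
  segs_a <- list(); segs_b <- list(); cell_of <- list(); name_of <- list()
  tpl <- list(PN_A = cell_template("PN_A", params),
              PN_C = cell_template("PN_C", params),
              FSI = cell_template("FSI", params))
  lens <- lapply(tpl, function(tp) {
    cfg <- if (tp$archetype == "FSI") params$cells$fsi else params$cells$pn
    vapply(cfg$compartments, function(cc) cc$length, 0)
  })
  for (i in seq_len(nrow(cells))) {
    ty <- cells$type[i]
    L <- lens[[ty]]
    p <- c(cells$x[i], cells$y[i], cells$z[i])
    u <- c(cells$ox[i], cells$oy[i], cells$oz[i])
    u <- u / sqrt(sum(u^2))
    hs <- L[1] / 2
    A <- list(p - hs * u); B <- list(p + hs * u)
    if (length(L) >= 2) { A[[2]] <- p + hs * u; B[[2]] <- p + (hs + L[2]) * u }
    if (length(L) >= 3) { A[[3]] <- p - hs * u; B[[3]] <- p - (hs + L[3]) * u }
    segs_a[[i]] <- do.call(rbind, A); segs_b[[i]] <- do.call(rbind, B)
    cell_of[[i]] <- rep(i, length(L)); name_of[[i]] <- tpl[[ty]]$comp_names
  }
  list(a = do.call(rbind, segs_a), b = do.call(rbind, segs_b),
       cell = unlist(cell_of), comp = unlist(name_of))
}

#' LFP forward-model coefficients for a network
#'
#' Line-source transfer coefficients from every compartment to every
#' electrode (mV per nA of outward transmembrane current).
#'
#' @param network a `bl_network`.
#' @param electrodes electrode positions, um (matrix, one row each).
#' @param sigma extracellular conductivity, S/m.
#' @param guard minimum radial distance, um.
#' @return matrix (total compartments x electrodes).
#' @export
lfp_coefficients <- function(network, electrodes, sigma = 0.3, guard = NULL) {
  sg <- comp_segments(network)
  electrodes <- matrix(as.numeric(electrodes), ncol = 3)
  if (is.null(guard)) guard <- 1
  out <- matrix(0, nrow(sg$a), nrow(electrodes))
  for (e in seq_len(nrow(electrodes)))
    out[, e] <- line_source_coef(sg$a, sg$b, electrodes[e, ], sigma, guard)
  out
}

#' Compute LFPs from recorded transmembrane currents
#'
#' Linear superposition of the line-source potentials of every recorded
#' compartment (1-ms resolution).
#'
#' @param traces a `bl_traces` with `record_imem = TRUE`.
#' @param network the simulated network.
#' @param electrodes electrode positions, um.
#' @param sigma conductivity, S/m.
#' @param scale multiplicative correction factor (density correction);
#'   default 1.
#' @param cells optional subset of cell ids contributing (default all).
#' @return object of class `bl_lfp`: `t` (ms), `phi` (mV, time x electrode),
#'   `electrodes`, and metadata.
#' @export
compute_lfp <- function(traces, network, electrodes, sigma = 0.3, scale = 1,
                        cells = NULL) {
  if (is.null(traces$imem) || !ncol(traces$imem))
    stop("traces were recorded without per-compartment currents")
  co <- lfp_coefficients(network, electrodes, sigma = sigma)
  if (!is.null(cells)) {
    sg <- comp_segments(network)
    co[!(sg$cell %in% cells), ] <- 0
  }
  phi <- traces$imem %*% co * scale
  structure(list(t = traces$t_ms, phi = phi,
                 electrodes = matrix(as.numeric(electrodes), ncol = 3),
                 sigma = sigma, scale = scale), class = "bl_lfp")
}

#' @export
print.bl_lfp <- function(x, ...) {
  cat(sprintf("<bl_lfp> %d electrodes, %d ms, correction factor %.3g\n",
              nrow(x$electrodes), length(x$t), x$scale))
  invisible(x)
}

#' LFP density correction factor
#'
#' The model fills the anatomical volume at a lower cell density than
#' tissue; its LFP amplitude is rescaled by `(tissue / model)^exponent`.
#'
#' @param tissue_density,model_density neurons per mm^3.
#' @param exponent empirical amplitude-vs-count scaling exponent.
#' @return multiplicative correction factor.
#' @export
density_correction <- function(tissue_density, model_density = 9840,
                               exponent = 0.67) {
  stopifnot(tissue_density > 0, model_density > 0)
  (tissue_density / model_density)^exponent
}

#' @rdname density_correction
#' @details `default_lfp_correction()` averages the factors for the two
#'   ends of the reported tissue-density range (2.5e4 and 2e5 per mm^3),
#'   giving the default scale applied to the model LFP (about 4.7).
#' @export
default_lfp_correction <- function(model_density = 9840, exponent = 0.67) {
  mean(c(density_correction(2.5e4, model_density, exponent),
         density_correction(2e5, model_density, exponent)))
}

#' Cell density of a network
#'
#' @param network a `bl_network` with box geometry.
#' @return neurons per mm^3.
#' @export
cell_density <- function(network) {
  if (is.null(network$box_um)) return(9840)
  nrow(network$cells) / (network$box_um / 1000)^3
}

#' Regular electrode grid inside the model volume
#'
#' @param box_um cube edge length, um.
#' @param n electrodes per side.
#' @param spacing inter-electrode spacing, um.
#' @param margin minimum distance from the box faces, um.
#' @return matrix (n^3 x 3) of positions; attribute `dims` holds the grid
#'   shape in x, y, z order (x varies fastest).
#' @export
electrode_grid <- function(box_um = 1400, n = 9, spacing = 125, margin = 200) {
  span <- (n - 1) * spacing
  if (span > box_um - 2 * margin)
    stop("grid span ", span, " um does not fit in the box with a ", margin,
         " um margin")
  start <- (box_um - span) / 2
  ax <- start + spacing * (seq_len(n) - 1)
  g <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  attr(g, "dims") <- c(n, n, n)
  g
}

#' Edge correction factors for an electrode grid
#'
#' Near the boundaries of the model the gamma bump in the spectrum shrinks;
#' per-electrode Z-scored gamma envelopes are rescaled by
#' `F_j = (GammaAmp_j / TotalAmp_j) / (GammaAmp_center / TotalAmp_center)`
#' where `GammaAmp` is the area under the gamma-band bump after removing a
#' power-law fit and `TotalAmp` the total spectral area.
#'
#' @param phi LFP matrix (time x electrodes), 1 kHz.
#' @param center column index of the central electrode.
#' @param band gamma band, Hz.
#' @param fs sampling rate, Hz.
#' @return numeric vector of per-electrode factors (center = 1). Electrodes
#'   with a degenerate power-law fit get factor 1 with a warning.
#' @export
edge_correction <- function(phi, center, band = c(60, 80), fs = 1000) {
  nelec <- ncol(phi)
  ratio <- vapply(seq_len(nelec), function(j) {
    ps <- welch_psd(phi[, j], fs = fs)
    tot <- sum(ps$power) * (ps$freq[2] - ps$freq[1])
    fit <- fit_power_law(ps$freq, ps$power, exclude = c(band[1] - 15, band[2] + 25))
    if (!is.finite(fit$a) || !is.finite(fit$alpha)) return(NA_real_)
    inb <- ps$freq >= band[1] & ps$freq <= band[2]
    resid <- ps$power[inb] - fit$a * ps$freq[inb]^(-fit$alpha)
    gam <- sum(pmax(resid, 0)) * (ps$freq[2] - ps$freq[1])
    gam / tot
  }, 0)
  if (anyNA(ratio)) {
    warning("degenerate power-law fit on ", sum(is.na(ratio)),
            " electrode(s); correction skipped there")
    ratio[is.na(ratio)] <- ratio[center]
  }
  ratio / ratio[center]
}


#' Re-estimate the LFP amplitude-versus-count scaling exponent
#'
#' Computes the SD of the LFP at one electrode from random cell
#' subsamples of increasing size and fits `SD ~ N^exponent` on log-log
#' axes.  The full-scale model reports an empirical exponent of about
#' 0.67; at reduced scale the estimate is reported, not asserted.
#'
#' @param traces a `bl_traces` with `record_imem = TRUE`.
#' @param network the simulated network.
#' @param electrode electrode position, um (length-3).
#' @param fractions cell-count fractions to sample.
#' @param seed subsampling seed.
#' @return list with `exponent`, and the per-fraction `n` and `sd`.
#' @export
estimate_density_exponent <- function(traces, network, electrode,
                                      fractions = c(0.2, 0.35, 0.5, 0.7, 1),
                                      seed = 1) {
  n_cell <- nrow(network$cells)
  sds <- withr_seed(seed, vapply(fractions, function(f) {
    ids <- sample(n_cell, round(f * n_cell))
    lf <- compute_lfp(traces, network, matrix(electrode, 1), cells = ids)
    stats::sd(lf$phi[, 1])
  }, 0))
  ns <- round(fractions * n_cell)
  fit <- stats::lm(log(sds) ~ log(ns))
  list(exponent = stats::coef(fit)[[2]], n = ns, sd = sds)
}
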