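#' Simulate a BL network
#'
#' Advances the full network state in fixed steps (default 50 us): implicit
#' voltage update across coupled compartments, exponential-Euler gating,
#' event-driven synapses with conduction delays, Ornstein-Uhlenbeck
#' background conductances, and gap junctions.  Deterministic under
#' `(network, seed)`: per-cell noise streams are derived from the master
#' seed by stable hashing of the cell index.
#'
#' @param network a [build_network()] object (or the single-cell/two-cell
#'   fixtures).
#' @param duration simulated time, ms (whole milliseconds).
#' @param seed master seed for all run-time randomness.
#' @param dt integration step, ms.
#' @param record_v cell ids whose somatic voltage is recorded.
#' @param v_every_step record voltage at every step instead of 1-ms samples.
#' @param vc_cells cell ids for shadow voltage-clamp recorders: their
#'   excitatory and inhibitory synaptic currents are reported as the clamp
#'   currents that would be measured at the EPSC (-75 mV) and IPSC (0 mV)
#'   holding potentials, without perturbing the cell.
#' @param clamp data.frame (`cell`, `hold`) of cells whose soma is pinned;
#'   the electrode current required to hold them is recorded (positive =
#'   outward injected current, so an EPSC appears as a negative deflection).
#' @param inj data.frame (`cell`, `comp`, `start`, `end`, `amp_nA`) of
#'   current steps.
#' @param afferent_trains list of afferent spike-time vectors (ms), length
#'   equal to the network's afferent count; `NULL` disables afferent drive.
#' @param electrodes matrix of electrode positions (um, one row per
#'   electrode); the LFP is accumulated on-line via the line-source forward
#'   model.
#' @param record_imem record per-compartment transmembrane currents (nA) at
#'   1-ms resolution (needed for [compute_lfp()] after the fact).
#' @param background enable the OU background conductances.
#' @param noise_scale named list of multipliers applied to the OU background
#'   (mean and SD together) per archetype and source:
#'   `pn_e`, `pn_i`, `fsi_e`, `fsi_i`.  Defaults to the packaged
#'   rate-matching calibration (`network_scale` in the noise config); pass
#'   `list()` for the uncalibrated table values.
#' @param audit track the maximum discrepancy between the axially-derived
#'   and physically-assembled per-compartment membrane currents.
#' @param sigma extracellular conductivity for the on-line LFP, S/m.
#' @param lfp_scale multiplicative LFP correction factor (see
#'   [density_correction()]); applied to the on-line LFP.
#' @return An object of class `bl_traces`: 1-ms `t`, voltage matrix `v`,
#'   spike raster `spikes` (`cell`, `t`), `epsc`/`ipsc` (nA), `lfp` (mV),
#'   optional `imem`, clamp currents, and bookkeeping needed by the
#'   analysis functions.
#' @export
simulate_network <- function(network, duration, seed, dt = 0.05,
                             record_v = integer(0), v_every_step = FALSE,
                             vc_cells = integer(0), clamp = NULL, inj = NULL,
                             afferent_trains = NULL, electrodes = NULL,
                             record_imem = FALSE, background = TRUE,
                             audit = FALSE, sigma = 0.3, lfp_scale = NULL,
                             noise_scale = NULL) {
  stopifnot(inherits(network, "bl_network"))
  params <- network$params
  if (abs(duration - round(duration)) > 1e-9 || duration < 0)
    stop("duration must be a whole number of milliseconds")
  n_steps <- round(duration / dt)

  type_names <- c("PN_A", "PN_C", "FSI")
  types <- match(network$cells$type, type_names) - 1L
  if (anyNA(types)) stop("unknown cell type in network")

  noise <- params$noise
  ns <- noise$network_scale
  if (is.null(ns)) ns <- list()
  if (!is.null(noise_scale)) ns[names(noise_scale)] <- noise_scale
  scl <- function(nm) if (is.null(ns[[nm]])) 1 else ns[[nm]]
  arch <- lapply(type_names, function(a) {
    tpl <- cell_template(a, params, dt = dt)
    ou <- if (a == "FSI") noise$fsi else noise$pn
    se <- if (a == "FSI") scl("fsi_e") else scl("pn_e")
    si <- if (a == "FSI") scl("fsi_i") else scl("pn_i")
    z <- if (background) 1 else 0
    tpl$ou <- list(ge0 = z * se * ou$excitatory$g0 / 1000,
                   ge_sd = z * se * ou$excitatory$sd / 1000,
                   taue = ou$excitatory$tau,
                   gi0 = z * si * ou$inhibitory$g0 / 1000,
                   gi_sd = z * si * ou$inhibitory$sd / 1000,
                   taui = ou$inhibitory$tau)
    unclass(tpl)
  })

  ed <- network$edges
  if (is.null(ed) || !nrow(ed)) {
    ed <- data.frame(src = integer(0), dst = integer(0), class = character(0),
                     w1 = numeric(0), w2 = numeric(0), delay_ms = numeric(0))
  }
  edges <- list(src = as.integer(ed$src - 1L), dst = as.integer(ed$dst - 1L),
                cls = syn_class_id(ed$class),
                w1 = as.double(ed$w1), w2 = as.double(ed$w2),
                delay_steps = as.integer(round(ed$delay_ms / dt)))

  af <- network$afferents
  n_aff <- network$n_afferents %||% 0L
  if (is.null(af) || !nrow(af) || is.null(afferent_trains)) {
    aff_edges <- list(aff = integer(0), dst = integer(0), cls = integer(0),
                      w1 = numeric(0), w2 = numeric(0), delay_steps = integer(0))
    aff_times <- numeric(0); aff_off <- rep(0L, n_aff + 1L)
  } else {
    if (length(afferent_trains) != n_aff)
      stop("afferent_trains must have length ", n_aff)
    aff_edges <- list(aff = as.integer(af$aff - 1L), dst = as.integer(af$dst - 1L),
                      cls = syn_class_id(af$class),
                      w1 = as.double(af$w1), w2 = as.double(af$w2),
                      delay_steps = as.integer(round(af$delay_ms / dt)))
    trains <- lapply(afferent_trains, function(x) sort(as.double(x)))
    aff_times <- unlist(trains, use.names = FALSE)
    if (is.null(aff_times)) aff_times <- numeric(0)
    aff_off <- c(0L, cumsum(vapply(trains, length, 0L)))
  }

  gp <- network$gaps
  gaps <- if (is.null(gp) || !nrow(gp)) {
    list(a = integer(0), b = integer(0), g_uS = numeric(0))
  } else {
    list(a = as.integer(gp$a - 1L), b = as.integer(gp$b - 1L),
         g_uS = as.double(gp$g_nS / 1000))
  }

  inj_l <- if (is.null(inj) || !nrow(inj)) {
    list(cell = integer(0), comp = integer(0), step0 = numeric(0),
         step1 = numeric(0), amp_nA = numeric(0))
  } else {
    list(cell = as.integer(inj$cell - 1L), comp = as.integer(inj$comp - 1L),
         step0 = round(inj$start / dt), step1 = round(inj$end / dt),
         amp_nA = as.double(inj$amp_nA))
  }

  clamp_l <- if (is.null(clamp) || !nrow(clamp)) {
    list(cell = integer(0), hold = numeric(0))
  } else {
    list(cell = as.integer(clamp$cell - 1L), hold = as.double(clamp$hold))
  }

  lfp_coef <- matrix(0, 0, 0)
  if (!is.null(electrodes)) {
    electrodes <- as.matrix(electrodes)
    if (is.null(lfp_scale))
      lfp_scale <- default_lfp_correction(cell_density(network))
    lfp_coef <- lfp_coefficients(network, electrodes, sigma = sigma) * lfp_scale
  }

  spk <- params$cells$spike_detection
  res <- cpp_simulate(list(
    dt = dt, n_steps = as.double(n_steps), seed = as.double(seed),
    on_ms = params$synapses$transmitter_on_ms,
    types = types, archetypes = lapply(arch, function(a) {
      a$dt <- dt
      list(c_nF = a$c_nF, gl_uS = a$gl_uS, el = a$el, gax_uS = a$gax_uS,
           channels = a$channels, ca = a$ca, syn_exc = a$syn_exc,
           syn_inh = a$syn_inh, ou = a$ou, dt = dt)
    }),
    classes = build_syn_classes(params, dt),
    edges = edges, aff_edges = aff_edges, n_afferents = as.integer(n_aff),
    aff_times = aff_times, aff_offsets = as.integer(aff_off),
    gaps = gaps, inj = inj_l, clamp = clamp_l,
    record_v = as.integer(record_v - 1L), v_every_step = v_every_step,
    vc_cells = as.integer(vc_cells - 1L),
    record_imem = record_imem, lfp_coef = lfp_coef, audit = audit,
    spike_threshold = spk$threshold, refractory_ms = spk$refractory
  ))

  t_ms <- seq_len(n_steps %/% round(1 / dt)) * 1
  structure(list(
    t = if (v_every_step) seq_len(n_steps) * dt else t_ms,
    t_ms = t_ms,
    v = res$v,
    spikes = data.frame(cell = res$spike_cell + 1L, t = res$spike_t),
    ca = res$ca,
    epsc = res$epsc, ipsc = res$ipsc,
    lfp = res$lfp, imem = res$imem, clamp_i = res$clamp_i,
    audit_max = res$audit_max, final_v = res$final_v,
    dt = dt, duration = duration, seed = seed,
    record_v = record_v, vc_cells = vc_cells,
    electrodes = electrodes,
    n_cells = nrow(network$cells)
  ), class = "bl_traces")
}

#' @export
print.bl_traces <- function(x, ...) {
  cat(sprintf("<bl_traces> %g ms, %d cells, %d spikes", x$duration,
              x$n_cells, nrow(x$spikes)))
  if (!is.null(x$lfp) && ncol(x$lfp)) cat(sprintf(", %d LFP electrodes", ncol(x$lfp)))
  cat("\n")
  invisible(x)
}

#' Population firing rates from a trace set
#'
#' @param traces a `bl_traces` object.
#' @param network the network it came from.
#' @param from discard spikes before this time (ms), e.g. a settling period.
#' @return data.frame with per-archetype mean rate (Hz).
#' @export
population_rates <- function(traces, network, from = 0) {
  dur_s <- (traces$duration - from) / 1000
  sp <- traces$spikes[traces$spikes$t > from, ]
  counts <- table(factor(network$cells$type[sp$cell],
                         levels = c("PN_A", "PN_C", "FSI")))
  n <- table(factor(network$cells$type, levels = c("PN_A", "PN_C", "FSI")))
  data.frame(type = names(n), n = as.integer(n),
             rate_hz = as.numeric(counts) / pmax(as.integer(n), 1) / dur_s)
}

#' Somatic voltage clamp of one cell
#'
#' Runs the network with the soma of `cell` pinned at `hold` and returns
#' the electrode current required to maintain it (1-ms resolution; positive
#' = outward injected current).
#'
#' @param network,duration,seed,... passed to [simulate_network()].
#' @param cell cell id to clamp.
#' @param hold holding potential, mV (within -100..20).
#' @return list with `t` (ms) and `i` (nA).
#' @export
voltage_clamp <- function(network, cell, hold, duration, seed = 1, ...) {
  stopifnot(hold >= -100, hold <= 20)
  tr <- simulate_network(network, duration, seed,
                         clamp = data.frame(cell = cell, hold = hold), ...)
  list(t = tr$t_ms, i = tr$clamp_i[, 1], traces = tr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- small fixture networks -------------------------------------------------

#' Single-cell and two-cell fixture networks
#'
#' `single_cell_network()` wraps one isolated cell; `two_fsi_network()`
#' couples two FSIs with a gap junction of the given conductance;
#' `motif_network()` builds an arbitrary small network from explicit cell
#' and edge tables (used for synapse-level tests).
#'
#' @param archetype cell archetype name.
#' @param params model parameters.
#' @return a `bl_network` object.
#' @export
single_cell_network <- function(archetype, params = bl_params()) {
  cells <- data.frame(type = archetype, x = 0, y = 0, z = 0,
                      ox = 0, oy = 0, oz = 1)
  structure(list(cells = cells, edges = NULL, gaps = NULL, afferents = NULL,
                 n_afferents = 0L, params = params), class = "bl_network")
}

#' @rdname single_cell_network
#' @param g_nS junctional conductance, nS.
#' @export
two_fsi_network <- function(g_nS, params = bl_params()) {
  cells <- data.frame(type = c("FSI", "FSI"), x = c(0, 50), y = 0, z = 0,
                      ox = 0, oy = 0, oz = 1)
  gaps <- data.frame(a = 1, b = 2, g_nS = g_nS)
  structure(list(cells = cells, edges = NULL, gaps = gaps, afferents = NULL,
                 n_afferents = 0L, params = params), class = "bl_network")
}

#' @rdname single_cell_network
#' @param cells data.frame with `type`, `x`, `y`, `z` (orientation columns
#'   `ox`, `oy`, `oz` optional, default +z).
#' @param edges data.frame with `src`, `dst`, `class`, `w1`, `w2`,
#'   `delay_ms` (may be `NULL`).
#' @param afferents optional afferent edge table (`aff`, `dst`, `class`,
#'   `w1`, `w2`, `delay_ms`) with `n_afferents` sources.
#' @param gaps optional gap table (`a`, `b`, `g_nS`).
#' @param n_afferents number of afferent sources.
#' @export
motif_network <- function(cells, edges = NULL, afferents = NULL, gaps = NULL,
                          n_afferents = 0L, params = bl_params()) {
  if (is.null(cells$ox)) { cells$ox <- 0; cells$oy <- 0; cells$oz <- 1 }
  structure(list(cells = cells, edges = edges, gaps = gaps,
                 afferents = afferents, n_afferents = as.integer(n_afferents),
                 params = params), class = "bl_network")
}
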