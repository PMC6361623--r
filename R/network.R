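#' Network recipes
#'
#' A recipe fixes cell counts, box geometry and afferent count.  The full
#' model has 27,000 cells (64% adapting PNs, 26% continuous PNs, 10% FSIs)
#' in a 1.4-mm cube with 1,800 extrinsic afferents.  `scale < 1` shrinks
#' the counts and the box edge together (edge scales as `scale^(1/3)`) so
#' that cell density, connection probabilities and spatial ranges are
#' preserved; the afferent count shrinks proportionally, which keeps the
#' per-PN extrinsic in-degree.
#'
#' @param scale fraction of the full cell count (1 = full model).
#' @param params a [bl_params()] list.
#' @return list of class `bl_recipe`.
#' @export
bl_recipe <- function(scale = 1, params = bl_params()) {
  comp <- params$network$composition
  n <- c(pn_a = comp$pn_a, pn_c = comp$pn_c, fsi = comp$fsi)
  ns <- round(n * scale)
  structure(list(
    n_pn_a = ns[["pn_a"]], n_pn_c = ns[["pn_c"]], n_fsi = ns[["fsi"]],
    box_um = params$network$geometry$box_um * scale^(1 / 3),
    min_dist = params$network$geometry$min_intersoma_um,
    n_afferents = round(params$network$afferents$count * scale),
    scale = scale, params = params
  ), class = "bl_recipe")
}

#' @rdname bl_recipe
#' @param n_total approximate total cell count for a reduced model (the
#'   published reduced model uses 1,000 neurons).
#' @export
reduced_recipe <- function(n_total = 1000, params = bl_params()) {
  comp <- params$network$composition
  bl_recipe(scale = n_total / (comp$pn_a + comp$pn_c + comp$fsi), params = params)
}

#' @export
print.bl_recipe <- function(x, ...) {
  cat(sprintf("<bl_recipe> %d PN_A + %d PN_C + %d FSI, box %.0f um, %d afferents\n",
              x$n_pn_a, x$n_pn_c, x$n_fsi, x$box_um, x$n_afferents))
  invisible(x)
}

#' Place cells in the model volume
#'
#' Rejection-sampled uniform placement in the cube honoring the minimum
#' intersoma spacing; archetype labels are randomly assigned in the exact
#' configured proportions, and each cell gets an isotropically random
#' dendrite orientation.
#'
#' @param recipe a [bl_recipe()].
#' @param seed placement seed.
#' @return data.frame with `type`, positions `x, y, z` (um) and unit
#'   orientation vectors `ox, oy, oz`.
#' @export
place_cells <- function(recipe, seed) {
  n <- recipe$n_pn_a + recipe$n_pn_c + recipe$n_fsi
  pos <- cpp_place_cells(n, recipe$box_um, recipe$min_dist, seed, 2000L)
  withr_seed(seed, {
    types <- sample(rep(c("PN_A", "PN_C", "FSI"),
                        c(recipe$n_pn_a, recipe$n_pn_c, recipe$n_fsi)))
    u <- matrix(stats::rnorm(3 * n), n, 3)
    u <- u / sqrt(rowSums(u^2))
    data.frame(type = types, x = pos[, 1], y = pos[, 2], z = pos[, 3],
               ox = u[, 1], oy = u[, 2], oz = u[, 3])
  })
}

# run code under a local R RNG state
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Axonal conduction delay
#'
#' `delay = distance / v + mini_del + U(-fluc, fluc) + dt`, with conduction
#' velocity 1 mm/ms, minimal delay 0.8 ms, fluctuation 0.1 ms and the
#' 0.05-ms step.  Uses R's RNG for the fluctuation.
#'
#' @param distance_um intersoma distance(s), um (non-negative).
#' @param params model parameters.
#' @return delay(s) in ms.
#' @export
conduction_delay <- function(distance_um, params = bl_params()) {
  if (any(distance_um < 0)) stop("negative distance")
  d <- params$network$delay
  distance_um / d$velocity_um_per_ms + d$mini_del +
    stats::runif(length(distance_um), -d$fluc, d$fluc) + d$dt
}

#' Wire the intrinsic network
#'
#' Realizes the stochastic connectivity: distance-binned PN-to-PN
#' probabilities (3/2/1/0.5% for <50/50-100/100-200/200-600 um), PN-FSI
#' pair outcomes within 300 um (34% FSI-to-PN only, 12% PN-to-FSI only,
#' 16% reciprocal), FSI-FSI electrical coupling (8%) and chemical
#' probabilities conditioned on coupling (50%/25% uni/bi if coupled,
#' 19%/3% if not).  Draws per-edge weights and conduction delays.
#'
#' @param cells a [place_cells()] table.
#' @param box_um box edge, um.
#' @param seed wiring seed.
#' @param params model parameters.
#' @param gap_g_nS gap junction conductance, nS (calibrated; see
#'   [calibrate_gap_conductance()]).
#' @return list with `edges` and `gaps` data.frames.
#' @export
wire_intrinsic <- function(cells, box_um, seed, params = bl_params(),
                           gap_g_nS = 1) {
  nw <- params$network
  types <- match(cells$type, c("PN_A", "PN_C", "FSI")) - 1L
  types[types == 1L] <- 0L  # PN_A and PN_C wire identically
  types[cells$type == "FSI"] <- 2L
  res <- cpp_wire_intrinsic(
    as.matrix(cells[, c("x", "y", "z")]), types,
    as.numeric(nw$pn_pn$breaks_um), as.numeric(nw$pn_pn$prob),
    nw$fsi_range_um,
    nw$pn_fsi$fsi_to_pn, nw$pn_fsi$pn_to_fsi, nw$pn_fsi$reciprocal,
    nw$fsi_fsi$electrical,
    nw$fsi_fsi$chemical_coupled$unidirectional, nw$fsi_fsi$chemical_coupled$bidirectional,
    nw$fsi_fsi$chemical_uncoupled$unidirectional, nw$fsi_fsi$chemical_uncoupled$bidirectional,
    box_um, seed)
  kinds <- c("pn_pn", "pn_fsi", "fsi_pn", "fsi_fsi")
  cls <- kinds[res$kind]
  edges <- withr_seed(seed + 1, {
    w1 <- numeric(length(cls)); w2 <- numeric(length(cls))
    for (k in kinds) {
      idx <- which(cls == k)
      if (!length(idx)) next
      spec <- params$synapses$classes[[k]]
      if (!is.null(spec$ampa)) {
        w1[idx] <- draw_weights(length(idx), spec$ampa$strength, params)
        w2[idx] <- draw_weights(length(idx), spec$nmda$strength, params)
      } else {
        w1[idx] <- draw_weights(length(idx), spec$gaba$strength, params)
      }
    }
    data.frame(src = res$src + 1L, dst = res$dst + 1L, class = cls,
               dist = res$dist, w1 = w1, w2 = w2,
               delay_ms = conduction_delay(res$dist, params))
  })
  gaps <- data.frame(a = res$gap_a + 1L, b = res$gap_b + 1L,
                     g_nS = rep(gap_g_nS, length(res$gap_a)))
  list(edges = edges, gaps = gaps)
}

#' Wire extrinsic afferents
#'
#' Each afferent contacts a fixed number of uniformly drawn PNs, plus each
#' FSI within range of any of those PNs with a small probability.
#'
#' @param cells placement table.
#' @param n_afferents number of afferent sources.
#' @param box_um box edge, um.
#' @param seed seed.
#' @param params model parameters.
#' @return data.frame with `aff`, `dst`, `class`, `w1`, `w2`, `delay_ms`.
#' @export
wire_afferents <- function(cells, n_afferents, box_um, seed, params = bl_params()) {
  av <- params$network$afferents
  types <- ifelse(cells$type == "FSI", 2L, 0L)
  res <- cpp_wire_afferents(as.matrix(cells[, c("x", "y", "z")]), types,
                            n_afferents, av$targets_per_afferent, av$fsi_prob,
                            params$network$fsi_range_um, box_um, seed)
  dst <- res$dst + 1L
  cls <- ifelse(cells$type[dst] == "FSI", "aff_fsi", "aff_pn")
  withr_seed(seed + 2, {
    w1 <- numeric(length(dst)); w2 <- numeric(length(dst))
    for (k in c("aff_pn", "aff_fsi")) {
      idx <- which(cls == k)
      if (!length(idx)) next
      spec <- params$synapses$classes[[k]]
      w1[idx] <- draw_weights(length(idx), spec$ampa$strength, params)
      w2[idx] <- draw_weights(length(idx), spec$nmda$strength, params)
    }
    data.frame(aff = res$aff + 1L, dst = dst, class = cls, w1 = w1, w2 = w2,
               delay_ms = conduction_delay(rep(0, length(dst)), params))
  })
}

#' Build a complete network from a recipe
#'
#' Placement, intrinsic wiring and afferent wiring under one master seed.
#'
#' @param recipe a [bl_recipe()].
#' @param seed master seed (placement, wiring, weights and delays derive
#'   from it deterministically).
#' @param gap_g_nS gap-junction conductance, nS; `NULL` calibrates it to
#'   the configured coupling coefficient (cached per session).
#' @return object of class `bl_network`.
#' @export
build_network <- function(recipe, seed, gap_g_nS = NULL) {
  params <- recipe$params
  if (is.null(gap_g_nS)) {
    gap_g_nS <- params$synapses$gap_junction$conductance
    if (is.null(gap_g_nS)) gap_g_nS <- cached_gap_conductance(params)
  }
  cells <- place_cells(recipe, seed)
  wi <- wire_intrinsic(cells, recipe$box_um, seed + 1000, params, gap_g_nS)
  af <- wire_afferents(cells, recipe$n_afferents, recipe$box_um, seed + 2000, params)
  structure(list(cells = cells, edges = wi$edges, gaps = wi$gaps,
                 afferents = af, n_afferents = recipe$n_afferents,
                 box_um = recipe$box_um, recipe = recipe, seed = seed,
                 params = params), class = "bl_network")
}

.blg_cache <- new.env(parent = emptyenv())

cached_gap_conductance <- function(params) {
  key <- "gap_g"
  if (is.null(.blg_cache[[key]])) {
    .blg_cache[[key]] <- calibrate_gap_conductance(
      params$synapses$gap_junction$coupling_coefficient, params)
  }
  .blg_cache[[key]]
}

#' @export
print.bl_network <- function(x, ...) {
  tt <- table(x$cells$type)
  cat(sprintf("<bl_network> %d cells (%s), %d edges, %d gap junctions, %d afferents\n",
              nrow(x$cells),
              paste(sprintf("%s=%d", names(tt), tt), collapse = ", "),
              if (is.null(x$edges)) 0L else nrow(x$edges),
              if (is.null(x$gaps)) 0L else nrow(x$gaps),
              x$n_afferents))
  invisible(x)
}

#' In-degree summary of a network
#'
#' @param network a `bl_network`.
#' @return data.frame with mean/SD in-degree per (target archetype, edge
#'   class).
#' @export
indegree_summary <- function(network) {
  ed <- network$edges
  n <- nrow(network$cells)
  is_fsi <- network$cells$type == "FSI"
  out <- list()
  for (k in unique(ed$class)) {
    idx <- ed$class == k
    tgt_fsi <- k %in% c("pn_fsi", "fsi_fsi")
    deg <- tabulate(ed$dst[idx], nbins = n)[if (tgt_fsi) is_fsi else !is_fsi]
    out[[k]] <- data.frame(class = k, target = if (tgt_fsi) "FSI" else "PN",
                           mean = mean(deg), sd = stats::sd(deg))
  }
  af <- network$afferents
  if (!is.null(af) && nrow(af)) {
    for (tgt in c("PN", "FSI")) {
      sel <- if (tgt == "FSI") is_fsi else !is_fsi
      deg <- tabulate(af$dst, nbins = n)[sel]
      out[[paste0("aff_", tgt)]] <- data.frame(class = "afferent", target = tgt,
                                               mean = mean(deg), sd = stats::sd(deg))
    }
  }
  do.call(rbind, out)
}
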