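#' Read and write spike trains as two-column text
#'
#' Plain whitespace-separated text with columns `id` and `time_ms`.
#'
#' @param spikes data.frame (`cell`/`id`, `t`/`time_ms`) or list of
#'   spike-time vectors.
#' @param path file path.
#' @export
write_spike_trains <- function(spikes, path) {
  if (is.list(spikes) && !is.data.frame(spikes)) {
    spikes <- data.frame(
      id = rep(seq_along(spikes), lengths(spikes)),
      time_ms = unlist(spikes, use.names = FALSE))
  } else {
    names(spikes)[1:2] <- c("id", "time_ms")
  }
  utils::write.table(spikes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spike_trains
#' @param as_list return a list of per-id spike-time vectors instead of a
#'   data.frame.
#' @param n_ids list length when `as_list = TRUE` (ids without spikes get
#'   empty vectors).
#' @export
read_spike_trains <- function(path, as_list = FALSE, n_ids = NULL) {
  d <- utils::read.table(path, header = TRUE)
  if (!as_list) return(d)
  if (is.null(n_ids)) n_ids <- max(d$id)
  out <- rep(list(numeric(0)), n_ids)
  sp <- split(d$time_ms, factor(d$id, levels = seq_len(n_ids)))
  for (i in seq_len(n_ids)) out[[i]] <- sort(as.numeric(sp[[i]]))
  out
}

#' Serialize a network to plain-text tables
#'
#' Writes placement (`cells.csv`), chemical edges (`edges.csv`), gap
#' junctions (`gaps.csv`) and afferent edges (`afferents.csv`) plus a small
#' `meta.csv`; [read_network()] restores a functionally identical network.
#'
#' @param network a `bl_network`.
#' @param dir output directory (created if needed).
#' @export
write_network <- function(network, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, f) if (!is.null(x)) utils::write.csv(x, file.path(dir, f), row.names = FALSE)
  wr(cbind(id = seq_len(nrow(network$cells)), network$cells), "cells.csv")
  wr(network$edges, "edges.csv")
  wr(network$gaps, "gaps.csv")
  wr(network$afferents, "afferents.csv")
  utils::write.csv(data.frame(box_um = network$box_um %||% NA,
                              n_afferents = network$n_afferents %||% 0L),
                   file.path(dir, "meta.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_network
#' @param params parameter set to attach to the restored network.
#' @export
read_network <- function(dir, params = bl_params()) {
  rd <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) utils::read.csv(p) else NULL
  }
  cells <- rd("cells.csv"); cells$id <- NULL
  meta <- rd("meta.csv")
  structure(list(cells = cells, edges = rd("edges.csv"), gaps = rd("gaps.csv"),
                 afferents = rd("afferents.csv"),
                 n_afferents = as.integer(meta$n_afferents),
                 box_um = if (is.na(meta$box_um)) NULL else meta$box_um,
                 params = params), class = "bl_network")
}

#' Write and read multichannel LFP series
#'
#' The potential matrix goes to `<stem>.csv` (column per electrode, 1-ms
#' rows) with the electrode geometry in `<stem>_electrodes.csv`.
#'
#' @param lfp a `bl_lfp` (or list with `t`, `phi`, `electrodes`).
#' @param stem output path stem.
#' @export
write_lfp <- function(lfp, stem) {
  utils::write.csv(data.frame(t_ms = lfp$t, lfp$phi), paste0(stem, ".csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(x = lfp$electrodes[, 1], y = lfp$electrodes[, 2],
                              z = lfp$electrodes[, 3]),
                   paste0(stem, "_electrodes.csv"), row.names = FALSE)
  invisible(stem)
}

#' @rdname write_lfp
#' @export
read_lfp <- function(stem) {
  d <- utils::read.csv(paste0(stem, ".csv"))
  e <- utils::read.csv(paste0(stem, "_electrodes.csv"))
  structure(list(t = d$t_ms, phi = as.matrix(d[, -1, drop = FALSE]),
                 electrodes = as.matrix(e), sigma = NA, scale = NA),
            class = "bl_lfp")
}
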