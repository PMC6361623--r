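#' Model parameter tables
#'
#' All fixed model constants (cell geometry, channel densities, synaptic
#' connection classes, wiring rules, background-noise parameters) live in
#' declarative YAML files under `inst/params/`.  `bl_params()` loads them
#' and returns a single nested list; individual files can be overridden to
#' explore parameter changes.
#'
#' @param cells,synapses,network,noise optional paths to replacement YAML
#'   files; defaults are the packaged tables.
#' @return A nested list with elements `cells`, `synapses`, `network`,
#'   `noise`.
#' @export
bl_params <- function(cells = NULL, synapses = NULL, network = NULL, noise = NULL) {
  pf <- function(path, default) {
    if (is.null(path)) path <- system.file("params", default, package = "blgamma")
    yaml::read_yaml(path)
  }
  structure(list(
    cells = pf(cells, "cells.yaml"),
    synapses = pf(synapses, "synapses.yaml"),
    network = pf(network, "network.yaml"),
    noise = pf(noise, "noise.yaml")
  ), class = "bl_params")
}

#' @export
print.bl_params <- function(x, ...) {
  comp <- x$network$composition
  cat("BL model parameter set\n")
  cat(sprintf("  cells: %d PN_A + %d PN_C + %d FSI in a %.0f um cube\n",
              comp$pn_a, comp$pn_c, comp$fsi, x$network$geometry$box_um))
  cat(sprintf("  synapse classes: %s\n",
              paste(names(x$synapses$classes), collapse = ", ")))
  invisible(x)
}

# channel name -> engine code
.chan_codes <- c(na = 1L, dr = 2L, m = 3L, ca = 4L, nap = 5L, a = 6L, h = 7L,
                 sahp = 8L, na_fs = 9L, dr_fs = 10L)

.chan_erev <- function(name, rev) {
  switch(name,
         na = rev$na, nap = rev$na, na_fs = rev$na,
         dr = rev$k, m = rev$k, a = rev$k, sahp = rev$k, dr_fs = rev$k,
         ca = rev$ca, h = rev$h,
         stop("unknown channel: ", name))
}
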