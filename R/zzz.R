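#' blgamma: biophysical simulation and analysis of BL gamma oscillations
#'
#' Conductance-based network model of the rat basolateral amygdala with a
#' line-source LFP forward model and the spectral / burst / entrainment
#' analysis toolbox used to characterize its transient gamma rhythm.
#'
#' @useDynLib blgamma, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @keywords internal
"_PACKAGE"
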