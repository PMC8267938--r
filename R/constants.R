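#' Physical constants and unit conversions
#'
#' `kB_kcal` is the Boltzmann constant in kcal mol^-1 K^-1, the unit system
#' used for all free energies in this package. `kj_to_kcal()` converts
#' kJ mol^-1 inputs (the convention of metadynamics configuration files) to
#' kcal mol^-1 using the thermochemical calorie (1 kcal = 4.184 kJ).
#'
#' @name constants
#' @keywords internal
NULL

kB_kcal <- 0.0019872041

kj_to_kcal <- function(x) x / 4.184

`%||%` <- function(a, b) if (is.null(a)) b else a
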