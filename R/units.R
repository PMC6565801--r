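#' Unit conversion constants
#'
#' Exact conversion constants used throughout the package. Geometry is held
#' in mm, pressure in Pa, flow in mm^3/s; physiological interfaces accept
#' mmHg, cmH2O and L/min.
#'
#' @format Named numeric vector with elements
#' \describe{
#'   \item{PA_PER_MMHG}{Pascal per mmHg (133.322387415).}
#'   \item{PA_PER_CMH2O}{Pascal per cmH2O (98.0665).}
#'   \item{MM3S_PER_LMIN}{mm^3/s per L/min (1e6 / 60).}
#' }
#' @export
unit_constants <- c(
  PA_PER_MMHG  = 133.322387415,
  PA_PER_CMH2O = 98.0665,
  MM3S_PER_LMIN = 1e6 / 60
)

#' Convert mmHg to Pa
#' @param x pressure in mmHg
#' @return pressure in Pa
#' @export
mmHg_to_Pa <- function(x) x * unit_constants[["PA_PER_MMHG"]]

#' Convert cmH2O to Pa
#' @param x pressure in cmH2O
#' @return pressure in Pa
#' @export
cmH2O_to_Pa <- function(x) x * unit_constants[["PA_PER_CMH2O"]]

#' Convert Pa to cmH2O
#' @param x pressure in Pa
#' @return pressure in cmH2O
#' @export
Pa_to_cmH2O <- function(x) x / unit_constants[["PA_PER_CMH2O"]]

#' Convert L/min to mm^3/s
#' @param x flow in L/min
#' @return flow in mm^3/s
#' @export
Lmin_to_mm3s <- function(x) x * unit_constants[["MM3S_PER_LMIN"]]
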