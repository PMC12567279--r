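#' @keywords internal
"_PACKAGE"

# Central unit conventions: volumes in L, flows and clearances in L/h,
# amounts in ug, concentrations in ug/L (numerically identical to ng/mL),
# times in h, doses in mg.

#' Convert a milligram dose to model mass units (ug)
#' @param dose_mg dose in mg
#' @return mass in ug
#' @keywords internal
mg_to_ug <- function(dose_mg) dose_mg * 1000

#' Convert an intrinsic clearance in uL/min to L/h
#' @param x clearance in uL/min
#' @return clearance in L/h
#' @keywords internal
ul_min_to_l_h <- function(x) x * 60 / 1e6

#' Convert a glomerular filtration rate in mL/min to L/h
#' @param x rate in mL/min
#' @return rate in L/h
#' @keywords internal
ml_min_to_l_h <- function(x) x * 60 / 1000

stop_domain <- function(...) stop(..., call. = FALSE)

#' Path to a packaged fixture file
#'
#' @param file file name under `extdata`
#' @return absolute path to the fixture
#' @export
escipbpk_fixture <- function(file) {
  path <- system.file("extdata", file, package = "escipbpk")
  if (!nzchar(path)) stop_domain("fixture not found: ", file)
  path
}

read_named_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(df$value, df$name)
}

#' Trapezoidal area under a curve
#' @param x abscissa (strictly increasing)
#' @param y ordinate
#' @return the trapezoidal integral
#' @keywords internal
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}
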