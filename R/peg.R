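#' Water potential of a PEG-8000 solution
#'
#' Evaluates the Michel polynomial for polyethylene glycol 8000,
#' \deqn{\Psi = 0.129\,C^2 T - 14.0\,C^2 - 0.40\,C}{Psi = 0.129 C^2 T - 14.0 C^2 - 0.40 C}
#' where `C` is the PEG concentration in g PEG per g water, `T` the solution
#' temperature in degrees Celsius, and the result is the osmotic potential in
#' MPa (the coefficients are Michel's bar-scale values divided by ten, so the
#' polynomial yields MPa directly). At any temperature at or below 40 C the
#' potential is zero at zero concentration and strictly decreasing in
#' concentration.
#'
#' @param conc PEG-8000 concentration, g PEG per g water (non-negative,
#'   vectorised).
#' @param temp solution temperature, degrees Celsius. Values outside 0--40 C
#'   trigger an extrapolation warning.
#' @return Osmotic potential in MPa (non-positive for valid inputs).
#' @seealso [peg_concentration_for()] for the inverse, [peg_table()] for a
#'   preparation table.
#' @examples
#' peg_water_potential(0.25, 15)   # about -0.854 MPa
#' peg_water_potential(0.25, 30)   # less negative when warmer
#' @export
peg_water_potential <- function(conc, temp) {
  if (!is.numeric(conc) || any(!is.finite(conc)))
    st_stop("st_domain_error", "`conc` must be finite numeric")
  if (any(conc < 0))
    st_stop("st_domain_error", "PEG concentration must be non-negative")
  if (!is.numeric(temp) || any(!is.finite(temp)))
    st_stop("st_domain_error", "`temp` must be finite numeric")
  if (any(temp < 0 | temp > 40))
    st_warn("st_extrapolation_warning",
            "temperature outside 0-40 C: extrapolating the PEG calibration")
  0.129 * conc^2 * temp - 14.0 * conc^2 - 0.40 * conc
}

#' PEG-8000 concentration achieving a target water potential
#'
#' Inverts the Michel polynomial: solves
#' `(0.129 T - 14.0) C^2 - 0.40 C - psi = 0` for the unique non-negative
#' root, so that `peg_water_potential(result, temp)` equals `target`.
#'
#' @param target target osmotic potential in MPa (non-positive, vectorised).
#' @param temp solution temperature, degrees Celsius; must satisfy
#'   `0.129 * temp < 14` so the quadratic is concave in the potential.
#' @return Concentration in g PEG-8000 per g water.
#' @examples
#' peg_concentration_for(-0.2, 15)   # about 0.1132 g/g
#' # a standard dilution series at 15 C:
#' peg_concentration_for(seq(0, -1, by = -0.2), 15)
#' @export
peg_concentration_for <- function(target, temp) {
  if (!is.numeric(target) || any(!is.finite(target)))
    st_stop("st_domain_error", "`target` must be finite numeric")
  if (any(target > 0))
    st_stop("st_domain_error", "target water potential must be <= 0 MPa")
  a <- 0.129 * temp - 14.0
  if (any(a >= 0))
    st_stop("st_domain_error",
            "temperature too high: the concentration term is not concave")
  # a C^2 - 0.4 C - target = 0, a < 0; the non-negative root:
  disc <- 0.16 + 4 * a * target
  if (any(disc < 0))
    st_stop("st_domain_error", "no non-negative root for this target/temperature")
  conc <- (0.4 - sqrt(disc)) / (2 * a)
  # guard tiny negative round-off at target == 0
  pmax(conc, 0)
}

#' Preparation table for a PEG-8000 dilution series
#'
#' @param targets vector of target potentials, MPa (non-positive).
#' @param temps vector of temperatures, degrees Celsius.
#' @return A data frame with one row per (target, temperature) pair:
#'   `psi_MPa`, `temp_C`, `conc_g_per_g`.
#' @export
peg_table <- function(targets = seq(0, -1, by = -0.2), temps = 15) {
  grid <- expand.grid(psi_MPa = targets, temp_C = temps,
                      KEEP.OUT.ATTRS = FALSE)
  grid$conc_g_per_g <- peg_concentration_for(grid$psi_MPa, grid$temp_C)
  grid
}
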