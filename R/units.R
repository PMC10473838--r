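# Global unit conventions: energies kcal/mol, lengths Angstrom, angles
# degrees, charges in elementary charge units, temperatures Kelvin.

#' Physical constants used throughout the package
#'
#' `KB` is the Boltzmann constant in kcal/(mol K); `COULOMB` is the
#' electrostatic conversion factor in kcal A / (mol e^2), so that
#' `COULOMB * q1 * q2 / r` is an energy in kcal/mol when `r` is in Angstrom.
#'
#' @format Named numeric scalars.
#' @keywords internal
#' @name constants
NULL

KB <- 0.0019872041
COULOMB <- 332.0637

#' Thermal energy at a temperature
#' @param temperature Temperature in Kelvin.
#' @return k_B T in kcal/mol.
#' @keywords internal
kbt <- function(temperature) KB * temperature

# Wrap angles (degrees) into (-180, 180].
wrap_angle <- function(x) {
  y <- x - 360 * floor((x + 180) / 360)
  y[y <= -180] <- y[y <= -180] + 360
  y
}

# Minimum-image difference a - b for a mix of periodic (360-degree) and
# aperiodic axes; `periodic` is a logical vector recycled over columns.
min_image_diff <- function(a, b, periodic) {
  d <- a - b
  if (any(periodic)) {
    if (is.matrix(d)) {
      for (j in which(rep_len(periodic, ncol(d)))) d[, j] <- wrap_angle(d[, j])
    } else if (periodic[1L]) {
      d <- wrap_angle(d)
    }
  }
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)
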