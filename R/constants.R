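#' Physical-constant and unit-conversion convention
#'
#' All kinetic and energetic formulas in the package draw their constants from
#' a single convention object, so that the whole analysis can be re-run under a
#' different set of constants (older CODATA releases, a different calorie) by
#' injection rather than by edits. Defaults are CODATA 2018 with the
#' thermochemical calorie (4.184 J).
#'
#' @param boltzmann Boltzmann constant, J K^-1.
#' @param planck Planck constant, J s.
#' @param gas_constant Molar gas constant, J mol^-1 K^-1.
#' @param light_speed Speed of light, cm s^-1 (CGS, as wavenumbers are cm^-1).
#' @param cal_to_joule Joules per thermochemical calorie.
#'
#' @return An object of class `kin_constants`: a list with the five constants
#'   plus derived helpers `kBT_over_h(T)` (s^-1), `kBT_in_wavenumbers(T)`
#'   (cm^-1), `RT_kcal(T)` (kcal mol^-1) and `hartree_to_kcal` (kcal mol^-1
#'   per hartree).
#'
#' @examples
#' cc <- kin_constants()
#' cc$kBT_over_h(298.15)        # ~6.21e12 s^-1
#' cc$kBT_in_wavenumbers(298.15) # ~207.2 cm^-1
#' @export
kin_constants <- function(boltzmann = 1.380649e-23,
                          planck = 6.62607015e-34,
                          gas_constant = 8.31446261815324,
                          light_speed = 2.99792458e10,
                          cal_to_joule = 4.184) {
  vals <- c(boltzmann = boltzmann, planck = planck,
            gas_constant = gas_constant, light_speed = light_speed,
            cal_to_joule = cal_to_joule)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all physical constants must be finite and strictly positive",
         call. = FALSE)
  }
  obj <- list(
    boltzmann = boltzmann,
    planck = planck,
    gas_constant = gas_constant,
    light_speed = light_speed,
    cal_to_joule = cal_to_joule,
    # kcal/mol per hartree: E_h * N_A / (1000 * cal_to_joule) with
    # E_h = 4.3597447222071e-18 J, N_A = 6.02214076e23 / mol (CODATA 2018)
    hartree_to_kcal = 4.3597447222071e-18 * 6.02214076e23 /
      (1000 * cal_to_joule),
    kBT_over_h = function(temperature) {
      stopifnot(temperature > 0)
      boltzmann * temperature / planck
    },
    kBT_in_wavenumbers = function(temperature) {
      stopifnot(temperature > 0)
      boltzmann * temperature / (planck * light_speed)
    },
    RT_kcal = function(temperature) {
      stopifnot(temperature > 0)
      gas_constant * temperature / (1000 * cal_to_joule)
    }
  )
  structure(obj, class = "kin_constants")
}

#' @export
print.kin_constants <- function(x, ...) {
  cat("<kin_constants>\n")
  cat(sprintf("  k_B = %.6e J/K, h = %.6e J s, R = %.8f J/mol/K\n",
              x$boltzmann, x$planck, x$gas_constant))
  cat(sprintf("  c = %.6e cm/s, 1 cal = %.3f J\n",
              x$light_speed, x$cal_to_joule))
  cat(sprintf("  at 298.15 K: k_BT/h = %.4e s^-1, k_BT/hc = %.2f cm^-1\n",
              x$kBT_over_h(298.15), x$kBT_in_wavenumbers(298.15)))
  invisible(x)
}
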