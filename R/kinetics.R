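#' Wigner tunneling correction
#'
#' Multiplicative correction \eqn{\Gamma = 1 + \frac{1}{24}\left(\frac{h c
#' \tilde\nu_i}{k_B T}\right)^2} applied to classical transition-state-theory
#' rates to account for proton tunneling through the barrier, parameterised by
#' the magnitude of the imaginary wavenumber at the transition state.
#'
#' @param nu_imag Magnitude of the imaginary wavenumber at the TS, cm^-1
#'   (vectorised, must be >= 0).
#' @param temperature Absolute temperature, K.
#' @param constants A [kin_constants()] convention.
#'
#' @return Dimensionless Gamma >= 1, same length as `nu_imag`.
#' @examples
#' wigner_correction(1150.3) # ~2.28 at 298.15 K
#' @export
wigner_correction <- function(nu_imag, temperature = 298.15,
                              constants = kin_constants()) {
  if (any(!is.finite(temperature)) || any(temperature <= 0)) {
    stop("temperature must be > 0", call. = FALSE)
  }
  if (any(nu_imag < 0, na.rm = TRUE)) {
    stop("nu_imag must be >= 0", call. = FALSE)
  }
  kbt_cm <- constants$kBT_in_wavenumbers(temperature)
  1 + (nu_imag / kbt_cm)^2 / 24
}

#' Eyring transition-state-theory rate constant
#'
#' \eqn{k = \Gamma \frac{k_B T}{h} e^{-\Delta\Delta G / RT}} for a
#' unimolecular step with Gibbs activation barrier in kcal mol^-1. Negative
#' barriers are computed rather than rejected (the rate then exceeds the
#' prefactor); classification of such barrierless steps is the caller's job,
#' see [classify_stability()].
#'
#' @param barrier_kcal Gibbs activation barrier, kcal mol^-1 (vectorised).
#' @param temperature Absolute temperature, K.
#' @param gamma Tunneling correction, >= 1 (vectorised; recycled).
#' @inheritParams wigner_correction
#'
#' @return Rate constant(s), s^-1.
#' @examples
#' eyring_rate(9.20, gamma = wigner_correction(1150.3)) # ~2.6e6 s^-1
#' @export
eyring_rate <- function(barrier_kcal, temperature = 298.15, gamma = 1,
                        constants = kin_constants()) {
  if (any(!is.finite(temperature)) || any(temperature <= 0)) {
    stop("temperature must be > 0", call. = FALSE)
  }
  if (any(gamma < 1, na.rm = TRUE)) {
    stop("gamma must be >= 1", call. = FALSE)
  }
  gamma * constants$kBT_over_h(temperature) *
    exp(-barrier_kcal / constants$RT_kcal(temperature))
}

#' Reverse Gibbs activation barrier
#'
#' Bookkeeping identity: the reverse barrier is the forward barrier minus the
#' reaction Gibbs energy (product minus reactant). May legitimately be
#' negative, in which case the product minimum is barrierless on the reverse
#' path.
#'
#' @param ddG_forward Forward activation barrier, kcal mol^-1.
#' @param dG_reaction Reaction Gibbs energy (product - reactant), kcal mol^-1.
#' @return Reverse barrier, kcal mol^-1.
#' @examples
#' reverse_barrier(96.31, 87.11) # 9.20
#' @export
reverse_barrier <- function(ddG_forward, dG_reaction) {
  ddG_forward - dG_reaction
}

#' Time to reach 99.9 % of the equilibrium composition
#'
#' For a reversible two-state interconversion the approach to equilibrium is
#' exponential with rate \eqn{k_f + k_r}; 99.9 % of the equilibrium
#' concentrations is reached after \eqn{\tau_{99.9\%} = \ln(10^3)/(k_f + k_r)}.
#'
#' @param k_forward,k_reverse Rate constants, s^-1 (vectorised).
#' @return Time, s.
#' @examples
#' equilibration_time(3.09e-58, 2.43e6) # ~2.84e-6 s
#' @export
equilibration_time <- function(k_forward, k_reverse) {
  total <- k_forward + k_reverse
  if (any(!(total > 0), na.rm = TRUE)) {
    stop("k_forward + k_reverse must be > 0", call. = FALSE)
  }
  log(1000) / total
}

#' Lifetime of the product tautomer
#'
#' Reciprocal of the reverse rate constant, 1/k_r.
#'
#' @param k_reverse Reverse rate constant, s^-1 (vectorised, > 0).
#' @return Lifetime, s.
#' @examples
#' lifetime(2.43e6) # ~4.12e-7 s
#' @export
lifetime <- function(k_reverse) {
  if (any(!(k_reverse > 0), na.rm = TRUE)) {
    stop("k_reverse must be > 0", call. = FALSE)
  }
  1 / k_reverse
}

#' Equilibrium constant from the reaction Gibbs energy
#'
#' \eqn{K_{eq} = e^{-\Delta G / RT}}. Consistent with the Eyring form: for any
#' shared tunneling correction and prefactor, `k_forward / k_reverse` equals
#' this value exactly (detailed balance).
#'
#' @inheritParams reverse_barrier
#' @inheritParams wigner_correction
#' @return Dimensionless equilibrium constant.
#' @export
equilibrium_constant <- function(dG_reaction, temperature = 298.15,
                                 constants = kin_constants()) {
  if (any(!is.finite(temperature)) || any(temperature <= 0)) {
    stop("temperature must be > 0", call. = FALSE)
  }
  exp(-dG_reaction / constants$RT_kcal(temperature))
}

#' Scale a harmonic wavenumber
#'
#' Harmonic vibrational wavenumbers are conventionally multiplied by an
#' empirical scale factor to correct for anharmonicity and the level of
#' theory; the default 0.9668 is the factor appropriate to
#' B3LYP/6-311++G(d,p) harmonic frequencies.
#'
#' @param nu Wavenumber, cm^-1 (>= 0, vectorised).
#' @param factor Dimensionless scale factor, > 0.
#' @return Scaled wavenumber, cm^-1.
#' @export
scale_wavenumber <- function(nu, factor = 0.9668) {
  if (any(nu < 0, na.rm = TRUE)) stop("nu must be >= 0", call. = FALSE)
  if (any(!(factor > 0))) stop("factor must be > 0", call. = FALSE)
  nu * factor
}

#' Period of a vibrational mode
#'
#' \eqn{T = 1/(c\,\tilde\nu)} for a mode of wavenumber nu (cm^-1). Used as the
#' dynamical yardstick: a tautomer whose lifetime is shorter than the period
#' of its lowest-frequency torsional mode cannot sustain vibrational
#' structure.
#'
#' @param nu Wavenumber, cm^-1, > 0 (vectorised).
#' @inheritParams wigner_correction
#' @return Period, s.
#' @examples
#' vibrational_period(20) # ~1.67e-12 s
#' @export
vibrational_period <- function(nu, constants = kin_constants()) {
  if (any(!(nu > 0), na.rm = TRUE)) stop("nu must be > 0", call. = FALSE)
  1 / (constants$light_speed * nu)
}

#' Dynamic-stability classification of a tautomer
#'
#' Three-way classification of the product of a tautomerization step:
#' `"barrierless_reverse"` when the reverse Gibbs barrier is <= 0 (the product
#' is not a kinetically protected minimum at all); `"dynamically_unstable"`
#' when a lowest torsional wavenumber is supplied and the product lifetime is
#' shorter than that mode's period (the minimum cannot develop vibrational
#' structure within its lifetime); `"stable"` otherwise. Precedence:
#' barrierless_reverse > dynamically_unstable > stable. Without a supplied
#' `lowest_mode` the function never returns `"dynamically_unstable"` — no
#' threshold is invented.
#'
#' @param ddG_reverse Reverse Gibbs barrier, kcal mol^-1 (vectorised).
#' @param tau_lifetime Product lifetime 1/k_r, s (vectorised).
#' @param lowest_mode Lowest torsional wavenumber, cm^-1, or `NA`/`NULL` when
#'   unknown.
#' @inheritParams wigner_correction
#' @return Character vector over
#'   `c("stable", "dynamically_unstable", "barrierless_reverse")`.
#' @examples
#' classify_stability(-1.20, 1.2e-14)             # barrierless_reverse
#' classify_stability(0.90, 3.02e-13, lowest_mode = 20) # dynamically_unstable
#' @export
classify_stability <- function(ddG_reverse, tau_lifetime, lowest_mode = NULL,
                               constants = kin_constants()) {
  n <- max(length(ddG_reverse), length(tau_lifetime))
  ddG_reverse <- rep_len(ddG_reverse, n)
  tau_lifetime <- rep_len(tau_lifetime, n)
  if (is.null(lowest_mode) || all(is.na(lowest_mode))) {
    lowest_mode <- rep_len(NA_real_, n)
  } else {
    lowest_mode <- rep_len(lowest_mode, n)
  }
  out <- rep_len("stable", n)
  unstable <- !is.na(lowest_mode) & !is.na(tau_lifetime) &
    tau_lifetime < vibrational_period(pmax(lowest_mode, .Machine$double.xmin),
                                      constants)
  out[unstable] <- "dynamically_unstable"
  out[!is.na(ddG_reverse) & ddG_reverse <= 0] <- "barrierless_reverse"
  out
}

#' Full kinetic characterisation of a set of tautomerization reactions
#'
#' Data-frame-first composition of the kinetic formulas: for each reaction row
#' the Wigner correction is evaluated from the imaginary wavenumber, forward
#' and reverse Eyring rates from the forward barrier and the derived reverse
#' barrier (both sharing the same tunneling correction), and from those the
#' equilibrium constant, product lifetime, 99.9 % equilibration time and
#' stability class.
#'
#' @param reactions A data frame with at least columns `name`, `nu_imag`
#'   (cm^-1), `ddG_forward` and `dG_reaction` (kcal mol^-1). A
#'   [reaction_set()] may be given directly, in which case its `$reactions`
#'   table is used. An optional `lowest_mode` column (cm^-1) feeds the
#'   dynamic-stability test.
#' @param temperature Absolute temperature, K. A `temperature` column in
#'   `reactions`, if present, takes precedence row-wise.
#' @param use_scaled_nu If `TRUE`, multiply `nu_imag` by `scale_factor` before
#'   the Wigner correction. Off by default: supplied wavenumbers are taken as
#'   the ones meant for the tunneling formula.
#' @param scale_factor Harmonic scale factor used when `use_scaled_nu = TRUE`.
#' @inheritParams wigner_correction
#'
#' @return A tibble with one row per reaction: the input identifiers and
#'   barriers plus `gamma`, `k_forward`, `k_reverse`, `K_eq`, `ddG_reverse`,
#'   `tau_lifetime`, `tau_999` and `stability`.
#' @examples
#' load_fixture("table1") |> compute_kinetics()
#' @export
compute_kinetics <- function(reactions, temperature = 298.15,
                             use_scaled_nu = FALSE, scale_factor = 0.9668,
                             constants = kin_constants()) {
  if (inherits(reactions, "reaction_set")) reactions <- reactions$reactions
  reactions <- tibble::as_tibble(reactions)
  needed <- c("name", "nu_imag", "ddG_forward", "dG_reaction")
  missing_cols <- setdiff(needed, names(reactions))
  if (length(missing_cols) > 0) {
    stop("reactions is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(reactions) == 0) {
    return(tibble::tibble(
      name = character(), nu_imag = double(), ddG_forward = double(),
      dG_reaction = double(), ddG_reverse = double(), temperature = double(),
      gamma = double(), k_forward = double(), k_reverse = double(),
      K_eq = double(), tau_lifetime = double(), tau_999 = double(),
      stability = character()
    ))
  }
  temp <- if ("temperature" %in% names(reactions)) {
    dplyr::coalesce(reactions$temperature, temperature)
  } else {
    rep_len(temperature, nrow(reactions))
  }
  nu <- if (use_scaled_nu) {
    scale_wavenumber(reactions$nu_imag, scale_factor)
  } else {
    reactions$nu_imag
  }
  lowest <- if ("lowest_mode" %in% names(reactions)) {
    reactions$lowest_mode
  } else {
    NULL
  }
  gamma <- wigner_correction(nu, temp, constants)
  ddG_rev <- reverse_barrier(reactions$ddG_forward, reactions$dG_reaction)
  k_f <- eyring_rate(reactions$ddG_forward, temp, gamma, constants)
  k_r <- eyring_rate(ddG_rev, temp, gamma, constants)
  out <- tibble::tibble(
    name = reactions$name,
    nu_imag = reactions$nu_imag,
    ddG_forward = reactions$ddG_forward,
    dG_reaction = reactions$dG_reaction,
    ddG_reverse = ddG_rev,
    temperature = temp,
    gamma = gamma,
    k_forward = k_f,
    k_reverse = k_r,
    K_eq = equilibrium_constant(reactions$dG_reaction, temp, constants),
    tau_lifetime = lifetime(k_r),
    tau_999 = equilibration_time(k_f, k_r),
    stability = classify_stability(ddG_rev, lifetime(k_r), lowest, constants)
  )
  class(out) <- c("tautkin_kinetics", class(out))
  out
}

#' Invert an Eyring rate back to its Gibbs barrier
#'
#' Algebraic inverse of [eyring_rate()]:
#' \eqn{\Delta\Delta G = -RT \ln\left(k / (\Gamma k_B T / h)\right)}. Used for
#' parameter-recovery checks on synthetic reaction sets.
#'
#' @param rate Rate constant, s^-1, > 0.
#' @inheritParams eyring_rate
#' @return Barrier, kcal mol^-1.
#' @export
invert_rate_to_barrier <- function(rate, temperature = 298.15, gamma = 1,
                                   constants = kin_constants()) {
  if (any(!(rate > 0), na.rm = TRUE)) stop("rate must be > 0", call. = FALSE)
  -constants$RT_kcal(temperature) *
    log(rate / (gamma * constants$kBT_over_h(temperature)))
}
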