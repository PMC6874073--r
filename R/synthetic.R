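# Seeded generator of synthetic reaction sets with the statistical structure
# of the reference tautomerization network: barriers spanning ~0.9-96.5
# kcal/mol, imaginary wavenumbers ~800-2200 cm^-1, and class-conditional BCP
# densities. Sampling within intervals is uniform — the reference tables give
# ranges, not distributions, so no distributional shape is invented.

run_seeded <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specification for the synthetic reaction generator
#'
#' Ranges default to the span of the reference tables; sampling is uniform
#' within each interval. A single global `seed` governs everything, with
#' per-record substreams derived by counter so that insertion order never
#' changes the draws of other records.
#'
#' @param n_reactions Number of reactions to generate.
#' @param barrier_range Forward Gibbs barrier interval, kcal mol^-1.
#' @param dG_fraction_range Fraction of the forward barrier assigned to the
#'   reaction Gibbs energy (values < 1 keep the reverse barrier positive).
#' @param p_exothermic_reverse Probability that a reaction instead draws its
#'   reaction energy *above* the forward barrier, producing a negative
#'   reverse barrier (a barrierless reverse path) by construction.
#' @param nu_range Imaginary-wavenumber interval, cm^-1.
#' @param rho_by_class Named list of density intervals (a.u.) per contact
#'   class.
#' @param contacts_per_structure Integer range of contacts drawn per
#'   stationary point.
#' @param contaminant_fraction Fraction of contacts emitted with a
#'   non-positive Laplacian, for validator tests.
#' @param temperature K.
#' @param seed Integer seed.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n_reactions = 10,
                       barrier_range = c(0.9, 96.5),
                       dG_fraction_range = c(0.0, 0.99),
                       p_exothermic_reverse = 0,
                       nu_range = c(800, 2200),
                       rho_by_class = list(
                         OH_O = c(0.020, 0.060),
                         CH2_O = c(0.100, 0.130),
                         CH_O = c(0.010, 0.022),
                         OH_C = c(0.010, 0.022),
                         vdW_OO = c(0.010, 0.030),
                         vdW_CO = c(0.010, 0.030)
                       ),
                       contacts_per_structure = c(1L, 4L),
                       contaminant_fraction = 0,
                       temperature = 298.15,
                       seed = 1L) {
  check_interval <- function(x, name, lower = -Inf) {
    if (length(x) != 2 || any(!is.finite(x)) || x[1] > x[2] || x[1] < lower) {
      stop("invalid interval for ", name, call. = FALSE)
    }
  }
  check_interval(barrier_range, "barrier_range")
  check_interval(dG_fraction_range, "dG_fraction_range")
  check_interval(nu_range, "nu_range", lower = 0)
  if (any(nu_range <= 0)) stop("nu_range must be positive", call. = FALSE)
  bad <- setdiff(names(rho_by_class), contact_classes)
  if (length(bad) > 0) {
    stop("rho_by_class names must be contact classes; unknown: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  for (cls in names(rho_by_class)) {
    check_interval(rho_by_class[[cls]], paste0("rho_by_class$", cls))
    if (any(rho_by_class[[cls]] <= 0)) {
      stop("rho intervals must be positive", call. = FALSE)
    }
  }
  if (p_exothermic_reverse < 0 || p_exothermic_reverse > 1 ||
      contaminant_fraction < 0 || contaminant_fraction > 1) {
    stop("p_exothermic_reverse and contaminant_fraction must be in [0, 1]",
         call. = FALSE)
  }
  structure(as.list(environment())[c(
    "n_reactions", "barrier_range", "dG_fraction_range",
    "p_exothermic_reverse", "nu_range", "rho_by_class",
    "contacts_per_structure", "contaminant_fraction", "temperature", "seed"
  )], class = "synth_spec")
}

runif1 <- function(range) stats::runif(1, range[1], range[2])

synth_contacts <- function(spec, label) {
  n <- sample(seq(spec$contacts_per_structure[1],
                  spec$contacts_per_structure[2]), 1)
  classes <- sample(names(spec$rho_by_class), n, replace = TRUE)
  purrr::map_dfr(seq_len(n), function(j) {
    cls <- classes[[j]]
    is_vdw <- cls %in% c("vdW_OO", "vdW_CO")
    contaminate <- stats::runif(1) < spec$contaminant_fraction
    d_hb <- if (is_vdw) NA_real_ else stats::runif(1, 1.3, 2.4)
    tibble::tibble(
      structure_label = label,
      donor_label = paste0(sub("_.*", "", cls), j),
      acceptor_label = paste0("A", j),
      contact_class = cls,
      rho = runif1(spec$rho_by_class[[cls]]),
      lap_rho = if (contaminate) stats::runif(1, -0.05, 0) else
        stats::runif(1, 0.01, 0.15),
      ellipticity = stats::runif(1, 0, 2),
      d_AB = if (is_vdw) stats::runif(1, 2.5, 3.1) else
        d_hb + stats::runif(1, 0.4, 1.0),
      d_HB = d_hb,
      angle_AHB = if (is_vdw) NA_real_ else stats::runif(1, 100, 160),
      V_bcp = NA_real_
    )
  })
}

#' Generate a synthetic reaction set
#'
#' Deterministic given the spec's seed. Each reaction carries a consistent
#' forward barrier, reaction energy and imaginary wavenumber; each of its
#' three stationary points carries 1-4 contacts with class-appropriate BCP
#' densities and positive Laplacians (unless a contaminant fraction is
#' requested, in which case that fraction of contacts draws a non-positive
#' Laplacian for validator tests). The output always passes
#' [validate_reaction_set()].
#'
#' @param spec A [synth_spec()].
#' @return A [reaction_set()].
#' @examples
#' rs <- generate_reactions(synth_spec(n_reactions = 5, seed = 42))
#' compute_kinetics(rs)
#' @export
generate_reactions <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  rows <- purrr::map(seq_len(spec$n_reactions), function(i) {
    run_seeded(spec$seed + i, {
      barrier <- runif1(spec$barrier_range)
      exo <- stats::runif(1) < spec$p_exothermic_reverse
      frac <- if (exo) stats::runif(1, 1.01, 1.30) else
        runif1(spec$dG_fraction_range)
      dG <- frac * barrier
      nu <- runif1(spec$nu_range)
      reactant <- sprintf("M%d", i)
      product <- sprintf("M%d*", i)
      name <- sprintf("%s↔%s", reactant, product)
      rx <- tibble::tibble(
        name = name, name_ascii = ascii_name(name),
        reactant = reactant, ts = paste0("TS_", name), product = product,
        nu_imag = nu,
        dG_reaction = dG,
        dE_reaction = dG + stats::runif(1, -1, 1),
        ddG_forward = barrier,
        ddE_forward = barrier + stats::runif(1, 0, 3),
        temperature = spec$temperature
      )
      labels <- c(reactant, rx$ts, product)
      st <- tibble::tibble(
        label = labels,
        role = c("minimum", "transition_state", "minimum"),
        rel_gibbs = c(0, barrier, dG),
        rel_electronic = c(0, rx$ddE_forward, rx$dE_reaction),
        dipole = stats::runif(3, 0.3, 10),
        dihedral_C3C2C1pC6p = stats::runif(3, -180, 180)
      )
      ct <- purrr::map_dfr(labels, function(lb) synth_contacts(spec, lb))
      list(rx = rx, st = st, ct = ct)
    })
  })
  reaction_set(
    reactions = dplyr::bind_rows(purrr::map(rows, "rx")),
    structures = dplyr::bind_rows(purrr::map(rows, "st")),
    contacts = dplyr::bind_rows(purrr::map(rows, "ct")),
    reference = list(kinetics = empty_ref_kinetics(),
                     contacts = empty_ref_contacts()),
    reference_label = if (spec$n_reactions > 0) "M1" else NA_character_,
    metadata = list(generator = "tautkin synthetic",
                    seed = as.character(spec$seed))
  )
}

#' Perturb the barriers of a reaction set with Gaussian noise
#'
#' Adds zero-mean Gaussian noise (sd `noise_sd`, kcal mol^-1) independently
#' to each forward barrier and reaction energy. The reverse barrier is a
#' derived quantity throughout the package, so the bookkeeping identity
#' `ddG_reverse = ddG_forward - dG_reaction` is preserved automatically.
#' `noise_sd = 0` is the exact identity.
#'
#' @param rs A [reaction_set()].
#' @param noise_sd Standard deviation of the noise, kcal mol^-1, >= 0.
#' @param seed Integer seed.
#' @return A perturbed [reaction_set()].
#' @export
perturb_fixture <- function(rs, noise_sd, seed = 1L) {
  stopifnot(inherits(rs, "reaction_set"), noise_sd >= 0)
  run_seeded(seed, {
    n <- nrow(rs$reactions)
    rs$reactions$ddG_forward <- rs$reactions$ddG_forward +
      stats::rnorm(n, 0, noise_sd)
    rs$reactions$dG_reaction <- rs$reactions$dG_reaction +
      stats::rnorm(n, 0, noise_sd)
    validate_reaction_set(rs)
  })
}
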