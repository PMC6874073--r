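#' Rank tautomerization pathways by forward activation barrier
#'
#' The probability ordering of competing proton-transfer routes is taken from
#' the forward Gibbs activation barrier (lowest barrier = most probable), not
#' from rates, so the ranking is independent of the constants convention.
#' Ties break alphabetically by reaction name.
#'
#' @param results A data frame with columns `name` and `ddG_forward` (a
#'   [compute_kinetics()] result, a reactions table, or a [reaction_set()]).
#' @return The input rows sorted by ascending `ddG_forward` with a `rank`
#'   column prepended; attributes `most_probable` and `least_probable` carry
#'   the extreme labels.
#' @examples
#' load_fixture("table1") |> compute_kinetics() |> rank_pathways()
#' @export
rank_pathways <- function(results) {
  if (inherits(results, "reaction_set")) results <- results$reactions
  results <- tibble::as_tibble(results)
  if (nrow(results) == 0) {
    stop("cannot rank an empty set of pathways", call. = FALSE)
  }
  out <- dplyr::arrange(results, .data$ddG_forward, .data$name)
  out <- dplyr::mutate(out, rank = dplyr::row_number(), .before = 1)
  attr(out, "most_probable") <- out$name[[1]]
  attr(out, "least_probable") <- out$name[[nrow(out)]]
  out
}

#' Compare computed kinetics against reference annotations
#'
#' Two distinct checks per annotated reaction. (1) Reproduction: rates
#' recomputed by [compute_kinetics()] against the printed `k_forward` /
#' `k_reverse`, as relative deviations judged at `tolerance_rel_rate`
#' (forward rates, which span dozens of orders of magnitude, are additionally
#' compared by base-10 exponent). (2) Internal consistency of the printed
#' columns themselves: `ln(1000)/(k_f + k_r)` and `1/k_r` evaluated from the
#' printed rates against the printed equilibration time and lifetime, and the
#' barrier bookkeeping `ddG_reverse = ddG_forward - dG_reaction`, judged at
#' the half-ulp of the printed 3-significant-figure values.
#'
#' @param rs A [reaction_set()] whose `reference$kinetics` block is populated.
#' @param tolerance_rel_rate Relative tolerance for rate reproduction
#'   (default 0.15, covering the unstated constants convention of the
#'   reference and the 2-decimal rounding of the printed barriers).
#' @inheritParams compute_kinetics
#' @return A tibble, one row per annotated reaction, with computed values,
#'   reference values, relative deviations and logical `pass_*` flags.
#' @export
compare_kinetics <- function(rs, tolerance_rel_rate = 0.15,
                             temperature = 298.15, use_scaled_nu = FALSE,
                             scale_factor = 0.9668,
                             constants = kin_constants()) {
  stopifnot(inherits(rs, "reaction_set"))
  ref <- rs$reference$kinetics
  computed <- compute_kinetics(rs, temperature = temperature,
                               use_scaled_nu = use_scaled_nu,
                               scale_factor = scale_factor,
                               constants = constants)
  if (is.null(ref) || nrow(ref) == 0) {
    return(dplyr::mutate(computed[0, ], ref_k_reverse = double(),
                         rel_dev_k_reverse = double()))
  }
  ref <- dplyr::rename_with(ref, ~ paste0("ref_", .x), -"name")
  joined <- dplyr::inner_join(computed, ref, by = "name")
  dplyr::mutate(
    joined,
    rel_dev_k_forward = .data$k_forward / .data$ref_k_forward - 1,
    rel_dev_k_reverse = .data$k_reverse / .data$ref_k_reverse - 1,
    exp_dev_k_forward = floor(log10(.data$k_forward)) -
      floor(log10(.data$ref_k_forward)),
    pass_k_reverse = abs(.data$rel_dev_k_reverse) <= tolerance_rel_rate,
    pass_k_forward_exponent = abs(.data$exp_dev_k_forward) <= 1,
    # identities evaluated on the printed rates themselves
    tau_999_from_ref = equilibration_time(.data$ref_k_forward,
                                          .data$ref_k_reverse),
    tau_from_ref = lifetime(.data$ref_k_reverse),
    pass_tau_999_identity =
      abs(.data$tau_999_from_ref / .data$ref_tau_999 - 1) <= 5e-3,
    pass_tau_identity =
      abs(.data$tau_from_ref / .data$ref_tau_lifetime - 1) <= 5e-3,
    pass_barrier_bookkeeping =
      abs(.data$ddG_reverse - .data$ref_ddG_reverse) <= 0.01 + 1e-9
  )
}

#' Compare computed contact energies against reference annotations
#'
#' Scores every contact with [score_contacts()] and joins the printed
#' energies from the set's reference block. Rows the reference itself marks
#' `flag_inconsistent` are expected mismatches: they count as anomalies, not
#' failures. EML-marked rows without a stored potential energy density are
#' unscorable and are reported with `NA` deviation.
#'
#' @param rs A [reaction_set()] with contacts and a populated
#'   `reference$contacts` block.
#' @param tolerance_energy Absolute tolerance, kcal mol^-1 (default 0.13, the
#'   half-ulp of a 3-decimal printed density propagated through the steeper
#'   linear slope).
#' @inheritParams score_contacts
#' @return A tibble with computed and reference energies, `abs_dev`, and
#'   flags `pass` (scored rows within tolerance), `anomaly` (flagged
#'   reference rows that indeed mismatch) and `unscorable`.
#' @export
compare_contacts <- function(rs, tolerance_energy = 0.13,
                             constants = kin_constants()) {
  stopifnot(inherits(rs, "reaction_set"))
  scored <- score_contacts(rs, tolerance = tolerance_energy,
                           constants = constants)
  ref <- rs$reference$contacts
  if (is.null(ref) || nrow(ref) == 0) {
    return(dplyr::mutate(scored, ref_energy = NA_real_, abs_dev = NA_real_,
                         pass = NA, anomaly = FALSE,
                         unscorable = is.na(.data$energy)))
  }
  ref <- dplyr::rename(ref, ref_energy = "energy",
                       ref_formula_mark = "formula_mark")
  joined <- dplyr::left_join(
    scored, ref, by = c("structure_label", "donor_label", "acceptor_label"))
  dplyr::mutate(
    joined,
    flag_inconsistent = dplyr::coalesce(.data$flag_inconsistent, FALSE),
    abs_dev = abs(.data$energy - .data$ref_energy),
    unscorable = .data$valid & is.na(.data$energy),
    anomaly = .data$flag_inconsistent & !is.na(.data$abs_dev) &
      .data$abs_dev > tolerance_energy,
    pass = dplyr::case_when(
      !is.na(.data$abs_dev) & !.data$flag_inconsistent ~
        .data$abs_dev <= tolerance_energy,
      .default = NA
    )
  )
}

format_sci <- function(x, digits = 3) {
  ifelse(is.na(x), NA_character_,
         formatC(signif(x, digits), digits = digits, format = "g"))
}

#' Run the full analysis and comparison pipeline
#'
#' Reads a reaction set (from a file path, a fixture name or an in-memory
#' [reaction_set()]), computes the kinetic characterisation of every reaction
#' and the energy of every bond-critical-point contact, ranks the pathways,
#' compares everything against whatever reference annotations the set
#' carries, and optionally writes a kinetics table and a contacts table as
#' TSV. Deterministic: rerunning with the same configuration byte-reproduces
#' the emitted tables.
#'
#' @param input A [reaction_set()], a path accepted by
#'   [read_reaction_set()], or a fixture name (`"table1"`, `"table2"`).
#' @param out_dir Directory for the emitted `kinetics.tsv` and
#'   `contacts.tsv`; `NULL` suppresses file output.
#' @param precision Significant digits used in the emitted tables (default 3,
#'   matching the reference tables' printed precision).
#' @inheritParams compare_kinetics
#' @inheritParams compare_contacts
#' @return An object of class `tautkin_report`: list with elements
#'   `kinetics`, `contacts` (computed tables), `ranking`,
#'   `comparison` (`$kinetics`, `$contacts`), `anomalies`, `pass`
#'   (overall logical; `NA` when no references were present) and `config`.
#' @examples
#' rep <- run_compute("table1")
#' rep$pass
#' @export
run_compute <- function(input, out_dir = NULL, temperature = 298.15,
                        use_scaled_nu = FALSE, scale_factor = 0.9668,
                        tolerance_rel_rate = 0.15, tolerance_energy = 0.13,
                        precision = 3, constants = kin_constants()) {
  stopifnot(tolerance_rel_rate > 0, tolerance_energy > 0, temperature > 0)
  rs <- if (inherits(input, "reaction_set")) {
    input
  } else if (is.character(input) && length(input) == 1 &&
             input %in% c("table1", "table2")) {
    load_fixture(input)
  } else {
    read_reaction_set(input)
  }
  kin <- compute_kinetics(rs, temperature = temperature,
                          use_scaled_nu = use_scaled_nu,
                          scale_factor = scale_factor, constants = constants)
  contacts <- score_contacts(rs, tolerance = tolerance_energy,
                             constants = constants)
  cmp_kin <- compare_kinetics(rs, tolerance_rel_rate = tolerance_rel_rate,
                              temperature = temperature,
                              use_scaled_nu = use_scaled_nu,
                              scale_factor = scale_factor,
                              constants = constants)
  cmp_ct <- compare_contacts(rs, tolerance_energy = tolerance_energy,
                             constants = constants)
  ranking <- if (nrow(kin) > 0) rank_pathways(kin) else kin

  pass_flags <- c(
    if (nrow(cmp_kin) > 0) {
      c(cmp_kin$pass_k_reverse, cmp_kin$pass_k_forward_exponent,
        cmp_kin$pass_tau_999_identity, cmp_kin$pass_tau_identity,
        cmp_kin$pass_barrier_bookkeeping)
    },
    if (nrow(cmp_ct) > 0) stats::na.omit(cmp_ct$pass)
  )
  pass <- if (length(pass_flags) == 0) NA else all(pass_flags)
  anomalies <- if (nrow(cmp_ct) > 0) {
    dplyr::filter(cmp_ct, .data$anomaly)
  } else {
    cmp_ct
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    kin_out <- dplyr::mutate(kin, dplyr::across(
      dplyr::where(is.numeric) & !dplyr::any_of("temperature"),
      ~ format_sci(.x, precision)))
    readr::write_tsv(kin_out, file.path(out_dir, "kinetics.tsv"))
    ct_out <- dplyr::mutate(contacts, dplyr::across(
      dplyr::any_of("energy"), ~ format_sci(.x, precision)))
    readr::write_tsv(ct_out, file.path(out_dir, "contacts.tsv"))
  }

  structure(
    list(kinetics = kin, contacts = contacts, ranking = ranking,
         comparison = list(kinetics = cmp_kin, contacts = cmp_ct),
         anomalies = anomalies, pass = pass,
         config = list(temperature = temperature,
                       use_scaled_nu = use_scaled_nu,
                       scale_factor = scale_factor,
                       tolerance_rel_rate = tolerance_rel_rate,
                       tolerance_energy = tolerance_energy,
                       precision = precision)),
    class = "tautkin_report"
  )
}

#' @export
print.tautkin_report <- function(x, ...) {
  cat("<tautkin_report>\n")
  cat(sprintf("  %d reaction(s) characterised, %d contact(s) scored\n",
              nrow(x$kinetics), nrow(x$contacts)))
  if (nrow(x$ranking) > 0) {
    cat(sprintf("  most probable pathway:  %s (ddG_forward = %.2f kcal/mol)\n",
                x$ranking$name[[1]], x$ranking$ddG_forward[[1]]))
    n <- nrow(x$ranking)
    cat(sprintf("  least probable pathway: %s (ddG_forward = %.2f kcal/mol)\n",
                x$ranking$name[[n]], x$ranking$ddG_forward[[n]]))
  }
  if (!is.na(x$pass)) {
    cat(sprintf("  reference comparison: %s (%d flagged anomal%s)\n",
                if (x$pass) "PASS" else "FAIL", nrow(x$anomalies),
                if (nrow(x$anomalies) == 1) "y" else "ies"))
  }
  invisible(x)
}

#' Tidy a pipeline report
#'
#' One row per compared quantity (rate reproduction and contact-energy
#' reproduction), broom-style: `item`, `quantity`, `computed`, `reference`,
#' `deviation` (relative for rates, absolute kcal mol^-1 for energies) and
#' `pass`.
#'
#' @param x A `tautkin_report`.
#' @param ... Unused.
#' @method tidy tautkin_report
#' @export
tidy.tautkin_report <- function(x, ...) {
  kin <- x$comparison$kinetics
  ct <- x$comparison$contacts
  out <- list()
  if (nrow(kin) > 0) {
    out$kf <- tibble::tibble(item = kin$name, quantity = "k_forward",
                             computed = kin$k_forward,
                             reference = kin$ref_k_forward,
                             deviation = kin$rel_dev_k_forward,
                             pass = kin$pass_k_forward_exponent)
    out$kr <- tibble::tibble(item = kin$name, quantity = "k_reverse",
                             computed = kin$k_reverse,
                             reference = kin$ref_k_reverse,
                             deviation = kin$rel_dev_k_reverse,
                             pass = kin$pass_k_reverse)
  }
  if (nrow(ct) > 0) {
    scored <- ct[!is.na(ct$ref_energy), , drop = FALSE]
    out$energy <- tibble::tibble(
      item = paste0(scored$structure_label, ": ", scored$donor_label,
                    "...", scored$acceptor_label),
      quantity = "contact_energy",
      computed = scored$energy, reference = scored$ref_energy,
      deviation = scored$abs_dev, pass = scored$pass)
  }
  dplyr::bind_rows(out)
}

#' Summarise a pipeline report in one row
#'
#' @inheritParams tidy.tautkin_report
#' @method glance tautkin_report
#' @export
glance.tautkin_report <- function(x, ...) {
  tibble::tibble(
    n_reactions = nrow(x$kinetics),
    n_contacts = nrow(x$contacts),
    n_anomalies = nrow(x$anomalies),
    most_probable = if (nrow(x$ranking) > 0) x$ranking$name[[1]] else
      NA_character_,
    min_ddG_forward = if (nrow(x$ranking) > 0) x$ranking$ddG_forward[[1]] else
      NA_real_,
    max_ddG_forward = if (nrow(x$ranking) > 0) {
      x$ranking$ddG_forward[[nrow(x$ranking)]]
    } else {
      NA_real_
    },
    pass = x$pass
  )
}

#' Barrier-ranking plot for a set of pathways
#'
#' Horizontal bars of forward and reverse Gibbs activation barriers, ordered
#' by forward barrier (most probable pathway on top), coloured by stability
#' class of the product.
#'
#' @param kinetics A [compute_kinetics()] result.
#' @return A ggplot object.
#' @export
plot_barriers <- function(kinetics) {
  ranked <- rank_pathways(kinetics)
  long <- tidyr::pivot_longer(
    dplyr::select(ranked, "name", "ddG_forward", "ddG_reverse", "stability"),
    c("ddG_forward", "ddG_reverse"),
    names_to = "direction", values_to = "barrier")
  long$direction <- sub("ddG_", "", long$direction)
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$barrier,
                               y = stats::reorder(.data$name, -.data$barrier,
                                                  FUN = min),
                               fill = .data$stability)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~direction, nrow = 1) +
    ggplot2::labs(x = expression(Delta * Delta * G ~ "(kcal/mol)"),
                  y = NULL, fill = "product stability") +
    ggplot2::theme_minimal()
}

#' Contact-energy plot
#'
#' Energy versus BCP electron density for scored contacts, coloured by the
#' empirical formula dispatched, with the two linear laws drawn across their
#' density ranges.
#'
#' @param scored A [score_contacts()] result.
#' @return A ggplot object.
#' @export
plot_contact_energies <- function(scored) {
  pts <- dplyr::filter(scored, !is.na(.data$energy))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$rho, y = .data$energy,
                                    colour = .data$formula_used)) +
    ggplot2::geom_function(fun = function(r) nbh_energy(pmax(r, 1e-6)),
                           colour = "grey60", linetype = 2) +
    ggplot2::geom_function(fun = function(r) byh_energy(pmax(r, 1e-6)),
                           colour = "grey30", linetype = 3) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = expression(rho ~ "at the (3,-1) BCP (a.u.)"),
                  y = "contact energy (kcal/mol)", colour = "formula") +
    ggplot2::theme_minimal()
}

#' @method autoplot tautkin_report
#' @export
autoplot.tautkin_report <- function(object, type = c("barriers", "contacts"),
                                    ...) {
  type <- match.arg(type)
  if (type == "barriers") {
    plot_barriers(object$kinetics)
  } else {
    plot_contact_energies(object$contacts)
  }
}

#' @method autoplot tautkin_kinetics
#' @export
autoplot.tautkin_kinetics <- function(object, ...) plot_barriers(object)
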