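#' Assemble a reaction set
#'
#' The package's central container: a validated bundle of tautomerization
#' reactions (reactant / transition state / product triples with Gibbs and
#' electronic energies and the imaginary TS wavenumber), the stationary
#' points they reference, and the bond-critical-point contacts of those
#' stationary points. Printed reference values (rate constants, lifetimes,
#' contact energies transcribed from a source table) live in a separate
#' `reference` block that no compute path reads — only the comparison
#' harness ([run_compute()], [compare_kinetics()], [compare_contacts()]).
#'
#' @param reactions Tibble with columns `name` (unique), `reactant`, `ts`,
#'   `product` (structure labels), `nu_imag` (cm^-1, > 0), `dG_reaction`,
#'   `dE_reaction`, `ddG_forward`, `ddE_forward` (kcal mol^-1) and
#'   `temperature` (K). `dG_reaction` is product-minus-reactant, positive when
#'   the product lies above the reactant.
#' @param structures Tibble with columns `label` (unique), `role`
#'   (`"minimum"` or `"transition_state"`), `rel_gibbs`, `rel_electronic`
#'   (kcal mol^-1, relative to `reference_label`), `dipole` (Debye, >= 0) and
#'   `dihedral_C3C2C1pC6p` (degrees).
#' @param contacts Tibble with columns `structure_label`, `donor_label`,
#'   `acceptor_label`, `contact_class` (one of [contact_classes]), `rho`
#'   (a.u., > 0), `lap_rho` (a.u.), `ellipticity` (>= 0), `d_AB` (Angstrom),
#'   `d_HB`, `angle_AHB` (may be `NA` for van der Waals contacts) and
#'   optionally `V_bcp` (a.u., <= 0).
#' @param reference List of reference-annotation tibbles: `kinetics` (keyed
#'   by reaction `name`: printed `ddG_reverse`, `ddE_reverse`, `k_forward`,
#'   `k_reverse`, `tau_999`, `tau_lifetime`) and `contacts` (keyed by
#'   `structure_label` + donor + acceptor: printed `energy`, the
#'   `formula_mark` used in the source, and a `flag_inconsistent` marker).
#' @param reference_label Label of the zero-energy structure.
#' @param metadata Free-form named list (method strings, scale factor, ...).
#'
#' @return A validated object of class `reaction_set`.
#' @seealso [read_reaction_set()], [load_fixture()], [generate_reactions()]
#' @export
reaction_set <- function(reactions = empty_reactions(),
                         structures = empty_structures(),
                         contacts = empty_contacts(),
                         reference = list(),
                         reference_label = NA_character_,
                         metadata = list()) {
  rs <- structure(
    list(
      reactions = tibble::as_tibble(reactions),
      structures = tibble::as_tibble(structures),
      contacts = tibble::as_tibble(contacts),
      reference = reference,
      reference_label = reference_label,
      metadata = metadata
    ),
    class = "reaction_set"
  )
  validate_reaction_set(rs)
}

#' @rdname reaction_set
#' @export
empty_reactions <- function() {
  tibble::tibble(
    name = character(), name_ascii = character(), reactant = character(),
    ts = character(), product = character(), nu_imag = double(),
    dG_reaction = double(), dE_reaction = double(), ddG_forward = double(),
    ddE_forward = double(), temperature = double()
  )
}

#' @rdname reaction_set
#' @export
empty_structures <- function() {
  tibble::tibble(
    label = character(), role = character(), rel_gibbs = double(),
    rel_electronic = double(), dipole = double(),
    dihedral_C3C2C1pC6p = double()
  )
}

#' @rdname reaction_set
#' @export
empty_contacts <- function() {
  tibble::tibble(
    structure_label = character(), donor_label = character(),
    acceptor_label = character(), contact_class = character(),
    rho = double(), lap_rho = double(), ellipticity = double(),
    d_AB = double(), d_HB = double(), angle_AHB = double(), V_bcp = double()
  )
}

#' ASCII-safe alias of a reaction or structure name
#'
#' Display names use the interconversion arrow and proton-transfer asterisks
#' (e.g. `"1↔1*_O1H"`); the alias replaces the arrow with `"__"` and each
#' asterisk with `"s"` (giving `"1__1s_O1H"`) so that file systems and shells
#' never see non-ASCII. Both forms are accepted anywhere a name is looked up.
#'
#' @param name Character vector of display names.
#' @return ASCII aliases.
#' @export
ascii_name <- function(name) {
  gsub("*", "s", gsub("↔", "__", name, fixed = TRUE), fixed = TRUE)
}

fail_record <- function(field, record, why) {
  stop(sprintf("invalid %s for record '%s': %s", field, record, why),
       call. = FALSE)
}

#' Validate a reaction set
#'
#' Enforces every structural invariant of the container: unique reaction
#' names, positive imaginary wavenumbers and temperatures, nonnegative
#' dipoles, positive BCP densities, donor-acceptor distances exceeding
#' hydrogen-acceptor distances, the closed contact-class enumeration,
#' resolvability of referenced structure labels, and the role bookkeeping
#' that ties each transition-state structure to exactly one imaginary
#' wavenumber through its owning reaction. Failures name the field and the
#' offending record.
#'
#' @param rs A `reaction_set`.
#' @return `rs`, invisibly usable, after passing all checks.
#' @export
validate_reaction_set <- function(rs) {
  stopifnot(inherits(rs, "reaction_set"))
  rx <- rs$reactions
  st <- rs$structures
  if (nrow(rx) > 0) {
    dup <- rx$name[duplicated(rx$name)]
    if (length(dup) > 0) fail_record("name", dup[1], "duplicated reaction name")
    bad <- which(!(rx$nu_imag > 0))
    if (length(bad) > 0) {
      fail_record("nu_imag", rx$name[bad[1]], "must be > 0")
    }
    bad <- which(!(rx$temperature > 0))
    if (length(bad) > 0) {
      fail_record("temperature", rx$name[bad[1]], "must be > 0")
    }
    if (nrow(st) > 0) {
      refs <- unique(c(rx$reactant, rx$ts, rx$product))
      known <- c(st$label, ascii_name(st$label))
      unresolved <- setdiff(c(refs, ascii_name(refs)), known)
      unresolved <- setdiff(refs, known)
      if (length(unresolved) > 0) {
        fail_record("structure reference", unresolved[1],
                    "label not present in structures table")
      }
      # each TS structure must be the saddle point of exactly one reaction,
      # which carries its single imaginary wavenumber
      ts_labels <- st$label[st$role == "transition_state"]
      owners <- table(rx$ts[rx$ts %in% ts_labels])
      multi <- names(owners)[owners > 1]
      if (length(multi) > 0) {
        fail_record("role", multi[1],
                    "transition_state owned by more than one reaction")
      }
    }
  }
  if (nrow(st) > 0) {
    dup <- st$label[duplicated(st$label)]
    if (length(dup) > 0) fail_record("label", dup[1], "duplicated structure label")
    bad <- which(!is.na(st$dipole) & st$dipole < 0)
    if (length(bad) > 0) fail_record("dipole", st$label[bad[1]], "must be >= 0")
    bad <- which(!st$role %in% c("minimum", "transition_state"))
    if (length(bad) > 0) {
      fail_record("role", st$label[bad[1]],
                  "must be 'minimum' or 'transition_state'")
    }
  }
  validate_contacts(rs$contacts)
  rs
}

validate_contacts <- function(ct) {
  if (nrow(ct) == 0) return(invisible(ct))
  rec <- paste(ct$structure_label, ct$donor_label, ct$acceptor_label,
               sep = " / ")
  bad <- which(!(ct$rho > 0))
  if (length(bad) > 0) fail_record("rho", rec[bad[1]], "must be > 0")
  bad <- which(!ct$contact_class %in% contact_classes)
  if (length(bad) > 0) {
    fail_record("contact_class", rec[bad[1]],
                paste("must be one of:", paste(contact_classes, collapse = ", ")))
  }
  bad <- which(!is.na(ct$d_AB) & !is.na(ct$d_HB) & !(ct$d_AB > ct$d_HB))
  if (length(bad) > 0) {
    fail_record("d_AB", rec[bad[1]], "must exceed d_HB when both present")
  }
  if ("ellipticity" %in% names(ct)) {
    bad <- which(!is.na(ct$ellipticity) & ct$ellipticity < 0)
    if (length(bad) > 0) {
      fail_record("ellipticity", rec[bad[1]], "must be >= 0")
    }
  }
  if ("V_bcp" %in% names(ct)) {
    bad <- which(!is.na(ct$V_bcp) & ct$V_bcp > 0)
    if (length(bad) > 0) fail_record("V_bcp", rec[bad[1]], "must be <= 0")
  }
  invisible(ct)
}

#' @export
print.reaction_set <- function(x, ...) {
  cat("<reaction_set>\n")
  cat(sprintf("  %d reaction(s), %d structure(s), %d contact(s)\n",
              nrow(x$reactions), nrow(x$structures), nrow(x$contacts)))
  if (!is.na(x$reference_label)) {
    cat(sprintf("  zero-energy reference structure: %s\n", x$reference_label))
  }
  has_ref <- vapply(x$reference, function(t) nrow(t) > 0, logical(1))
  if (any(has_ref)) {
    cat("  reference annotations:",
        paste(names(x$reference)[has_ref], collapse = ", "), "\n")
  }
  invisible(x)
}
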