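# Shared fixtures built in code.

# A two-reaction set exercising both a thermoneutral step and an endothermic
# step with a known reverse barrier.
tiny_reaction_set <- function() {
  rx <- tibble::tibble(
    name = c("A↔A*", "B↔B*"),
    name_ascii = ascii_name(name),
    reactant = c("A", "B"), ts = paste0("TS_", name),
    product = c("A*", "B*"),
    nu_imag = c(1000, 1500),
    dG_reaction = c(0, 5),
    dE_reaction = c(0, 5.5),
    ddG_forward = c(10, 12),
    ddE_forward = c(11, 13),
    temperature = 298.15
  )
  st <- tibble::tibble(
    label = unique(c(rx$reactant, rx$ts, rx$product)),
    role = c("minimum", "minimum", "transition_state", "transition_state",
             "minimum", "minimum"),
    rel_gibbs = NA_real_, rel_electronic = NA_real_,
    dipole = 1, dihedral_C3C2C1pC6p = 180
  )
  reaction_set(reactions = rx, structures = st,
               reference_label = "A",
               metadata = list(source = "unit-test"))
}

expect_reaction_set_equal <- function(a, b) {
  expect_equal(a$reactions, b$reactions)
  expect_equal(a$structures, b$structures)
  expect_equal(a$contacts, b$contacts)
  expect_equal(a$reference$kinetics, b$reference$kinetics)
  expect_equal(a$reference$contacts, b$reference$contacts)
  expect_equal(a$reference_label, b$reference_label)
  expect_equal(a$metadata, b$metadata)
}
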