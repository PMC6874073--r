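test_that("generation is deterministic in the seed and validates", {
  spec <- synth_spec(n_reactions = 10, seed = 1)
  a <- generate_reactions(spec)
  b <- generate_reactions(spec)
  expect_identical(nrow(a$reactions), 10L)
  expect_reaction_set_equal(a, b)
  expect_s3_class(validate_reaction_set(a), "reaction_set")
  c <- generate_reactions(synth_spec(n_reactions = 10, seed = 2))
  expect_false(identical(a$reactions$ddG_forward, c$reactions$ddG_forward))
})

test_that("per-record substreams make draws independent of set size", {
  small <- generate_reactions(synth_spec(n_reactions = 3, seed = 9))
  large <- generate_reactions(synth_spec(n_reactions = 6, seed = 9))
  expect_equal(small$reactions, large$reactions[1:3, ])
})

test_that("generated quantities stay inside their spec intervals", {
  spec <- synth_spec(n_reactions = 25, seed = 4)
  rs <- generate_reactions(spec)
  rx <- rs$reactions
  expect_true(all(rx$ddG_forward >= spec$barrier_range[1] &
                    rx$ddG_forward <= spec$barrier_range[2]))
  expect_true(all(rx$nu_imag >= spec$nu_range[1] &
                    rx$nu_imag <= spec$nu_range[2]))
  # reverse barriers stay positive without the exothermic-reverse option
  expect_true(all(reverse_barrier(rx$ddG_forward, rx$dG_reaction) > 0))
  # class-conditional densities respect their intervals
  ct <- rs$contacts
  for (cls in unique(ct$contact_class)) {
    iv <- spec$rho_by_class[[cls]]
    rho <- ct$rho[ct$contact_class == cls]
    expect_true(all(rho >= iv[1] & rho <= iv[2]))
  }
  expect_true(all(ct$lap_rho > 0))
})

test_that("exothermic-reverse option yields barrierless products downstream", {
  rs <- generate_reactions(synth_spec(n_reactions = 12, seed = 8,
                                      p_exothermic_reverse = 0.5))
  k <- compute_kinetics(rs)
  expect_gt(sum(k$stability == "barrierless_reverse"), 0)
  expect_true(all((k$ddG_reverse <= 0) ==
                    (k$stability == "barrierless_reverse")))
})

test_that("strong CH2...O contacts all dispatch to BYH above 10 kcal/mol", {
  spec <- synth_spec(n_reactions = 15, seed = 6,
                     rho_by_class = list(CH2_O = c(0.100, 0.130)))
  scored <- score_contacts(generate_reactions(spec))
  expect_gt(nrow(scored), 0)
  expect_true(all(scored$formula_used == "BYH"))
  expect_true(all(scored$energy > 10))
})

test_that("contaminant mode emits invalid contacts at a visible rate", {
  rs <- generate_reactions(synth_spec(n_reactions = 20, seed = 12,
                                      contaminant_fraction = 0.3))
  scored <- score_contacts(rs)
  frac <- mean(!scored$valid)
  expect_gt(frac, 0.1)
  expect_lt(frac, 0.5)
  # invalid rows are flagged and carry no energy
  expect_true(all(is.na(scored$energy[!scored$valid])))
})

test_that("barriers invert from generated rates to 1e-10", {
  rs <- generate_reactions(synth_spec(n_reactions = 20, seed = 3))
  k <- compute_kinetics(rs)
  expect_equal(invert_rate_to_barrier(k$k_forward, gamma = k$gamma),
               rs$reactions$ddG_forward, tolerance = 1e-10)
  expect_equal(invert_rate_to_barrier(k$k_reverse, gamma = k$gamma),
               k$ddG_reverse, tolerance = 1e-10)
})

test_that("perturbation is seeded, bounded, and the identity at sd zero", {
  rs <- load_fixture("table1")
  expect_reaction_set_equal(perturb_fixture(rs, 0, seed = 5), rs)
  p1 <- perturb_fixture(rs, 0.01, seed = 5)
  p2 <- perturb_fixture(rs, 0.01, seed = 5)
  expect_reaction_set_equal(p1, p2)
  expect_false(identical(p1$reactions$ddG_forward,
                         rs$reactions$ddG_forward))
  # rate perturbation is bounded by the Boltzmann factor of the noise
  k0 <- compute_kinetics(rs)
  k1 <- compute_kinetics(p1)
  noise <- abs(p1$reactions$ddG_forward - rs$reactions$ddG_forward)
  bound <- exp(noise / kin_constants()$RT_kcal(298.15))
  ratio <- k1$k_forward / k0$k_forward
  expect_true(all(pmax(ratio, 1 / ratio) <= bound * (1 + 1e-9)))
  expect_error(synth_spec(barrier_range = c(5, 1)), "interval")
  expect_error(synth_spec(nu_range = c(-10, 100)), "interval|positive")
})
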