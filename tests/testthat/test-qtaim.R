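test_that("QTAIM validity requires positive density and Laplacian", {
  expect_true(is_valid_contact(0.041, 0.124))
  expect_false(is_valid_contact(0.020, -0.01))
  expect_false(is_valid_contact(0, 0.1))
})

test_that("empirical energy formulas evaluate and stay monotone", {
  expect_equal(nbh_energy(0.041), 6.71, tolerance = 1e-2)
  expect_equal(nbh_energy(0.107), 22.48, tolerance = 1e-2)
  expect_equal(nbh_energy(3.09 / 239), 0)
  expect_equal(byh_energy(0.116), 28.46, tolerance = 1e-2)
  expect_equal(byh_energy(0.128), 31.44, tolerance = 1e-2)
  expect_equal(byh_energy(0.110), 26.97, tolerance = 1e-2)
  rho <- seq(0.01, 0.13, by = 0.005)
  expect_true(all(diff(nbh_energy(rho)) > 0))
  expect_true(all(diff(byh_energy(rho)) > 0))
  expect_error(nbh_energy(0), "rho")
  expect_error(byh_energy(-0.1), "rho")
})

test_that("EML energy converts the potential energy density magnitude", {
  expect_identical(eml_energy(0), 0)
  # hand unit conversion: 0.5 * 0.02 hartree -> kcal/mol
  expect_equal(eml_energy(-0.02), 0.5 * 0.02 * 627.5095, tolerance = 1e-6)
  expect_equal(eml_energy(-0.04), 2 * eml_energy(-0.02))
  expect_error(eml_energy(NA_real_), "EML-scored")
})

test_that("formula dispatch follows the contact class and strength rules", {
  ct <- tibble::tibble(
    structure_label = "S",
    donor_label = c("HC6H", "O5H", "C2'H", "O3H", "O5", "C9"),
    acceptor_label = c("O7", "O4", "O3", "C2'", "O4", "O1"),
    contact_class = c("CH2_O", "OH_O", "CH_O", "OH_C", "vdW_OO", "vdW_CO"),
    rho = c(0.116, 0.051, 0.018, 0.012, 0.012, 0.029),
    lap_rho = c(0.059, 0.148, 0.076, 0.045, 0.049, 0.090),
    V_bcp = c(NA, NA, NA, NA, -0.004, NA)
  )
  out <- score_contacts(ct)
  expect_identical(out$formula_used,
                   c("BYH", "NBH", "EML", "EML", "EML", "EML"))
  expect_equal(out$energy[1], 28.46, tolerance = 1e-2)
  expect_equal(out$energy[2], 9.10, tolerance = 1e-2)
  # weak CH...O without V is an explicit unscorable-EML outcome
  expect_true(is.na(out$energy[3]))
  expect_identical(out$formula_used[3], "EML")
  # vdW contact with a stored V is EML-scored
  expect_equal(out$energy[5], eml_energy(-0.004))
  expect_error(score_contacts(dplyr::mutate(ct, contact_class = "XX_O")),
               "unknown contact_class")
})

test_that("dispatch never returns BYH at or below 10 kcal/mol", {
  set.seed(5)
  ct <- tibble::tibble(
    structure_label = "S", donor_label = "CH", acceptor_label = "O",
    contact_class = sample(c("CH_O", "CH2_O"), 200, replace = TRUE),
    rho = runif(200, 0.005, 0.13),
    lap_rho = runif(200, 0.01, 0.15)
  )
  out <- score_contacts(ct)
  byh <- out[out$formula_used == "BYH" & !is.na(out$formula_used), ]
  expect_gt(nrow(byh), 0)
  expect_true(all(byh$energy > 10))
  # and the CH-type rows not sent to BYH would indeed fall at or below 10
  weak <- out[out$formula_used == "EML", ]
  expect_true(all(byh_energy(weak$rho) <= 10))
})

test_that("invalid contacts are flagged, never dropped, and order survives", {
  ct <- tibble::tibble(
    structure_label = "S",
    donor_label = c("O5H", "O3H", "C2'H"),
    acceptor_label = c("O4", "O4", "O3"),
    contact_class = c("OH_O", "OH_O", "CH_O"),
    rho = c(0.041, 0.027, 0.018),
    lap_rho = c(0.124, -0.01, 0.076)
  )
  out <- score_contacts(ct)
  expect_identical(nrow(out), 3L)
  expect_identical(out$valid, c(TRUE, FALSE, TRUE))
  expect_true(is.na(out$energy[2]))
  # permutation invariance: scoring row-wise does not depend on order
  perm <- c(3, 1, 2)
  out_perm <- score_contacts(ct[perm, ])
  expect_equal(out_perm$energy, out$energy[perm])
})

test_that("fixture contact energies reproduce the printed column", {
  cmp <- compare_contacts(load_fixture("table2"))
  scored <- cmp[!is.na(cmp$pass), ]
  # every NBH/BYH row within the rho-rounding tolerance
  expect_true(all(scored$pass))
  expect_true(all(scored$formula_used %in% c("NBH", "BYH")))
  # the computed formula agrees with the source's formula mark
  expect_identical(scored$formula_used, scored$ref_formula_mark)
  # the single inconsistent printed row is flagged, not silently matched
  anom <- cmp[cmp$anomaly, ]
  expect_identical(nrow(anom), 1L)
  expect_identical(anom$structure_label, "TS_5↔5*_C8H2")
  expect_equal(anom$energy, nbh_energy(0.026))
  expect_equal(anom$ref_energy, 6.78)
  # EML-marked rows carry no V in the source, hence stay unscorable
  eml <- cmp[cmp$ref_formula_mark == "EML", ]
  expect_true(all(eml$unscorable))
})

test_that("score_structure restricts to one stationary point in order", {
  rs <- load_fixture("table2")
  one <- score_structure(rs, "1")
  expect_identical(nrow(one), 3L)
  expect_identical(one$donor_label, c("O5H", "O3H", "C2'H"))
  expect_equal(one$energy[1], 6.71, tolerance = 1e-2)
  none <- score_structure(rs, "no-such-structure")
  expect_identical(nrow(none), 0L)
})

test_that("bare BCP CSV lists round through the standalone reader", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    structure_label = "S", donor_label = "O5H", acceptor_label = "O4",
    contact_class = "OH_O", rho = 0.041, lap_rho = 0.124,
    ellipticity = 0.0152, d_AB = 2.655, d_HB = 1.770, angle_AHB = 147.3,
    V_bcp = NA_real_), path)
  ct <- read_bcp_csv(path)
  expect_equal(score_contacts(ct)$energy, 6.71, tolerance = 1e-2)
})
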