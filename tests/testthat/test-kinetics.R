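test_that("constants convention reproduces the standard derived magnitudes", {
  cc <- kin_constants()
  expect_gt(cc$kBT_over_h(298.15), 6.20e12)
  expect_lt(cc$kBT_over_h(298.15), 6.22e12)
  expect_gt(cc$kBT_in_wavenumbers(298.15), 207.0)
  expect_lt(cc$kBT_in_wavenumbers(298.15), 207.4)
  expect_error(kin_constants(planck = -1), "positive")
})

test_that("Wigner correction matches hand evaluation and its limits", {
  cc <- kin_constants()
  expect_identical(wigner_correction(0), 1)
  # independent hand oracle: 1 + (nu / (k_B T / h c))^2 / 24
  kbt_cm <- cc$boltzmann * 298.15 / (cc$planck * cc$light_speed)
  expect_equal(wigner_correction(1150.3), 1 + (1150.3 / kbt_cm)^2 / 24)
  expect_equal(wigner_correction(1150.3), 2.284, tolerance = 1e-3)
  expect_equal(wigner_correction(2116.5), 5.347, tolerance = 1e-3)
  # strictly increasing in nu, strictly decreasing in T
  nus <- seq(0, 2500, by = 100)
  expect_true(all(diff(wigner_correction(nus)) > 0))
  expect_true(all(diff(wigner_correction(1000, temperature = c(250, 300, 350,
                                                               400))) < 0))
  expect_error(wigner_correction(100, temperature = 0), "temperature")
  expect_error(wigner_correction(-5), "nu_imag")
})

test_that("Eyring rate has the exact zero-barrier limit and is monotone", {
  cc <- kin_constants()
  expect_identical(eyring_rate(0, gamma = 1), cc$kBT_over_h(298.15))
  expect_equal(eyring_rate(9.20, gamma = wigner_correction(1150.3)),
               2.43e6, tolerance = 0.15)
  set.seed(7)
  barriers <- sort(runif(50, -5, 100))
  rates <- eyring_rate(barriers, gamma = 1.5)
  expect_true(all(diff(rates) < 0))
  expect_error(eyring_rate(5, gamma = 0.5), "gamma")
})

test_that("reverse barrier is the forward barrier minus the reaction energy", {
  expect_equal(reverse_barrier(96.31, 87.11), 9.20)
  expect_equal(reverse_barrier(92.66, 91.76), 0.90)
  expect_equal(reverse_barrier(13.10, 14.30), -1.20)
  expect_identical(reverse_barrier(42, 42), 0)
})

test_that("equilibration time and lifetime identities hold", {
  expect_equal(equilibration_time(3.09e-58, 2.43e6), 2.84e-6,
               tolerance = 5e-3)
  expect_equal(equilibration_time(1.64e-55, 3.31e12), 2.09e-12,
               tolerance = 5e-3)
  expect_equal(equilibration_time(log(1000), 0), 1)
  expect_error(equilibration_time(0, 0), "> 0")
  expect_equal(lifetime(2.43e6), 4.12e-7, tolerance = 5e-3)
  expect_equal(lifetime(3.21e8), 3.12e-9, tolerance = 5e-3)
  expect_identical(lifetime(1), 1)
  expect_error(lifetime(0), "> 0")
})

test_that("equilibrium constant obeys detailed balance with any shared gamma", {
  cc <- kin_constants()
  expect_identical(equilibrium_constant(0), 1)
  expect_equal(equilibrium_constant(87.11),
               exp(-87.11 / cc$RT_kcal(298.15)))
  expect_gt(equilibrium_constant(-1), 1)
  set.seed(11)
  for (i in 1:20) {
    ddGf <- runif(1, 0, 60)
    dG <- runif(1, -20, min(ddGf, 30))
    gam <- runif(1, 1, 6)
    ratio <- eyring_rate(ddGf, gamma = gam) /
      eyring_rate(reverse_barrier(ddGf, dG), gamma = gam)
    expect_equal(ratio, equilibrium_constant(dG), tolerance = 1e-10)
  }
})

test_that("wavenumber scaling and vibrational periods behave", {
  expect_equal(scale_wavenumber(1000), 966.8)
  expect_identical(scale_wavenumber(0, 0.5), 0)
  expect_identical(scale_wavenumber(2116.5, 1.0), 2116.5)
  expect_equal(vibrational_period(20), 1.668e-12, tolerance = 1e-3)
  expect_equal(vibrational_period(1), 3.336e-11, tolerance = 1e-3)
  expect_equal(vibrational_period(40), vibrational_period(20) / 2)
  expect_error(vibrational_period(0), "> 0")
})

test_that("stability classification applies its precedence rules", {
  # negative reverse barrier dominates everything
  expect_identical(classify_stability(-1.20, 1.24e-14, lowest_mode = 20),
                   "barrierless_reverse")
  # lifetime below the torsional period
  expect_identical(classify_stability(0.90, 3.02e-13, lowest_mode = 20),
                   "dynamically_unstable")
  expect_identical(classify_stability(10, 1, lowest_mode = 20), "stable")
  # without a supplied mode the dynamic test never fires
  expect_identical(classify_stability(0.90, 3.02e-13), "stable")
  expect_identical(
    classify_stability(c(-1, 5, 5), c(1, 1e-13, 1), lowest_mode = 20),
    c("barrierless_reverse", "dynamically_unstable", "stable"))
})

test_that("compute_kinetics composes the pieces consistently", {
  rs <- tiny_reaction_set()
  k <- compute_kinetics(rs)
  expect_s3_class(k, "tbl_df")
  expect_identical(nrow(k), 2L)
  # thermoneutral reaction: equal rates, unit equilibrium constant
  expect_equal(k$k_forward[1], k$k_reverse[1])
  expect_equal(k$K_eq[1], 1)
  # shared gamma, detailed balance
  expect_equal(k$k_forward / k$k_reverse, k$K_eq, tolerance = 1e-10)
  expect_equal(k$tau_lifetime * k$k_reverse, c(1, 1), tolerance = 1e-12)
  expect_true(all(k$tau_999 <=
                    log(1000) / pmax(k$k_forward, k$k_reverse) * (1 + 1e-12)))
  # optional pre-scaling of the wavenumber feeds the tunneling factor only
  ks <- compute_kinetics(rs, use_scaled_nu = TRUE)
  expect_equal(ks$gamma, wigner_correction(rs$reactions$nu_imag * 0.9668))
  expect_identical(compute_kinetics(empty_reactions()) |> nrow(), 0L)
  expect_error(compute_kinetics(data.frame(name = "x")), "missing column")
})

test_that("barrier inversion recovers Eyring inputs to 1e-10", {
  set.seed(3)
  barriers <- runif(30, -2, 95)
  gam <- wigner_correction(runif(30, 800, 2200))
  back <- invert_rate_to_barrier(eyring_rate(barriers, gamma = gam),
                                 gamma = gam)
  expect_equal(back, barriers, tolerance = 1e-10)
})
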