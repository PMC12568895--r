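test_that("disabled decay conserves deposited mass; one half-life halves a
           pulse", {
  masses <- random_congener_masses(61)
  em <- pulse_emissions(2000, masses)
  inf_hl <- soil_fate_params(uniform_half_lives(Inf), evaluation_year = 2022)
  expect_equal(unclass(residual_amount(em, inf_hl)), masses,
               tolerance = 1e-12, ignore_attr = TRUE)
  one_hl <- soil_fate_params(uniform_half_lives(22), evaluation_year = 2022)
  expect_equal(unclass(residual_amount(em, one_hl)), masses / 2,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("multi-year residuals equal a term-by-term hand sum", {
  hl <- read_half_lives_csv()
  set.seed(9)
  em <- rbind(pulse_emissions(1990, random_congener_masses(1)),
              pulse_emissions(1991, random_congener_masses(2)),
              pulse_emissions(1992, random_congener_masses(3)))
  params <- soil_fate_params(hl, deposition_fraction = 0.8,
                             sorption_factor = 0.9,
                             evaluation_year = 2022)
  res <- residual_amount(em, params)
  byhand <- setNames(numeric(17), congener_names())
  for (i in 1:17) for (y in 1990:1992)
    byhand[i] <- byhand[i] +
      em[as.character(y), i] * 0.8 * 0.9 * 2^(-(2022 - y) / hl[[i]])
  expect_equal(unclass(res), byhand, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("decay composes as a semigroup over elapsed time", {
  masses <- random_congener_masses(62)
  hl <- read_half_lives_csv()
  em <- pulse_emissions(2000, masses)
  r_direct <- residual_amount(em, soil_fate_params(hl, evaluation_year = 2015))
  r_mid <- residual_amount(em, soil_fate_params(hl, evaluation_year = 2006))
  em_mid <- pulse_emissions(2006, unclass(r_mid))
  r_two_step <- residual_amount(em_mid,
                                soil_fate_params(hl, evaluation_year = 2015))
  expect_equal(unclass(r_two_step), unclass(r_direct), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("residual fractions sum to one and emissions cannot postdate the
           evaluation year", {
  em <- pulse_emissions(2000, random_congener_masses(63))
  params <- soil_fate_params(read_half_lives_csv(), evaluation_year = 2022)
  expect_equal(sum(attr(residual_amount(em, params), "fraction")), 1)
  late <- soil_fate_params(read_half_lives_csv(), evaluation_year = 1999)
  expect_error(residual_amount(em, late), "evaluation year")
})

test_that("uncertainty bands are deterministic per seed, contain the point
           estimate, and collapse at zero variation", {
  em <- pulse_emissions(1995, random_congener_masses(64))
  params <- soil_fate_params(read_half_lives_csv(), evaluation_year = 2022)
  b1 <- residual_profile_uncertainty(em, params, n_samples = 500, seed = 5)
  b2 <- residual_profile_uncertainty(em, params, n_samples = 500, seed = 5)
  expect_identical(b1, b2)
  expect_true(all(b1$frac_lo <= b1$frac + 1e-12))
  expect_true(all(b1$frac_hi >= b1$frac - 1e-12))
  flat <- residual_profile_uncertainty(em, params, variation = c(0, 0),
                                       n_samples = 100, seed = 1)
  expect_equal(flat$frac_lo, flat$frac, tolerance = 1e-12)
  expect_equal(flat$frac_hi, flat$frac, tolerance = 1e-12)
  expect_error(residual_profile_uncertainty(em * 0, params), "empty")
})

test_that("widening the half-life variation range widens every band", {
  em <- pulse_emissions(1990, random_congener_masses(65))
  params <- soil_fate_params(read_half_lives_csv(), evaluation_year = 2022)
  narrow <- residual_profile_uncertainty(em, params,
                                         variation = c(-0.25, 0.5),
                                         n_samples = 4000, seed = 7)
  wide <- residual_profile_uncertainty(em, params,
                                       variation = c(-0.5, 1),
                                       n_samples = 4000, seed = 7)
  expect_true(all(wide$frac_hi - wide$frac_lo >=
                  narrow$frac_hi - narrow$frac_lo - 1e-9))
})

test_that("two-congener fraction quantiles match a quadrature oracle", {
  # all mass in two congeners, single pulse: the fraction of congener 1 is
  # f(m1, m2) = E1 2^(-a/(h1 m1)) / (E1 2^(-a/(h1 m1)) + E2 2^(-a/(h2 m2)))
  # with independent uniform multipliers; quantiles by dense grid quadrature
  masses <- setNames(rep(0, 17), congener_names())
  masses[1] <- 40; masses[17] <- 60
  em <- pulse_emissions(1992, masses)
  hl <- uniform_half_lives(30); hl[1] <- 10
  params <- soil_fate_params(hl, evaluation_year = 2022)
  mc <- residual_profile_uncertainty(em, params, n_samples = 20000, seed = 2)
  g <- seq(0.5 + 1 / 400, 2 - 1 / 400, length.out = 200)  # cell midpoints
  a <- 30
  r1 <- masses[[1]] * 2^(-a / (10 * g))
  r2 <- masses[[17]] * 2^(-a / (30 * g))
  f_grid <- outer(r1, r2, function(x, y) x / (x + y))
  q <- quantile(as.vector(f_grid), c(0.025, 0.975), names = FALSE)
  expect_equal(mc$frac_lo[1], q[1], tolerance = 0.01)
  expect_equal(mc$frac_hi[1], q[2], tolerance = 0.01)
})

test_that("residual TEQ delegates to the TEF tables", {
  zero <- structure(setNames(rep(0, 17), congener_names()),
                    class = "soil_residual")
  expect_equal(unname(residual_teq(zero)), c(0, 0))
  tcdd <- setNames(rep(0, 17), congener_names())
  tcdd["2,3,7,8-TeCDD"] <- 3.5
  expect_equal(unname(residual_teq(structure(tcdd, class = "soil_residual"))),
               c(3.5, 3.5))
  r <- random_congener_masses(66)
  tq <- residual_teq(structure(r, class = "soil_residual"))
  expect_equal(tq[["WHO2005"]], sum(r * tef_table("WHO2005")))
  expect_equal(tq[["WHO2022"]], sum(r * tef_table("WHO2022")))
})
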