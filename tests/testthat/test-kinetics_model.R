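ref_params <- function() kinetic_parameters("OCDF", k1 = 4.6e5, k2 = 0.1)

cond_at <- function(t, lambda = 1.2, e_cl = 0.007, e_metal = 0.03) {
  furnace_conditions(950, t, lambda, e_cl, e_metal)
}

test_that("generation vanishes at t = 0 and saturates at k1 E_Cl E_metal / k2", {
  p <- ref_params()
  expect_equal(congener_generation(p, cond_at(0)), 0)
  t_sat <- 50 / (p$k2 * 1.2)  # k2 lambda t = 50
  asym <- p$k1 * 0.007 * 0.03 / p$k2
  expect_equal(congener_generation(p, cond_at(t_sat)), asym,
               tolerance = 1e-20)
})

test_that("generation matches a numerical ODE oracle at finite t", {
  p <- ref_params()
  lambda <- 1.2
  rhs <- function(t, y, parms)
    list(lambda * (p$k1 * 0.007 * 0.03 - p$k2 * y))
  times <- c(0, 0.5, 2, 7, 30)
  sol <- deSolve::ode(c(P = 0), times, rhs, NULL,
                      rtol = 1e-12, atol = 1e-12)
  got <- vapply(times, function(t) congener_generation(p, cond_at(t)),
                numeric(1))
  expect_equal(got, unname(sol[, "P"]), tolerance = 1e-8)
})

test_that("the small-t first-order series holds to 1% when k2 lambda t < 0.02", {
  p <- ref_params()
  for (t in c(1e-4, 1e-3, 0.02 / (p$k2 * 1.2) * 0.99)) {
    lin <- p$k1 * 0.007 * 0.03 * 1.2 * t
    expect_equal(congener_generation(p, cond_at(t)), lin, tolerance = 0.01)
  }
})

test_that("generation is monotone in each driver and concave in time", {
  grid <- seq(0.2, 6, length.out = 12)
  p <- ref_params()
  gen_t <- vapply(grid, function(t) congener_generation(p, cond_at(t)),
                  numeric(1))
  expect_true(all(diff(gen_t) > 0))
  expect_true(all(diff(diff(gen_t)) < 0))  # concave
  for (fac in c("e_cl", "e_metal")) {
    vals <- vapply(seq(0.001, 0.05, length.out = 8), function(v) {
      args <- list(t = 2); args[[fac]] <- v
      congener_generation(p, do.call(cond_at, args))
    }, numeric(1))
    expect_true(all(diff(vals) > 0))
  }
  gen_l <- vapply(seq(0.5, 3, length.out = 8), function(l)
    congener_generation(p, cond_at(2, lambda = l)), numeric(1))
  expect_true(all(diff(gen_l) > 0))
  gen_k1 <- vapply(seq(1e4, 1e6, length.out = 8), function(k1)
    congener_generation(kinetic_parameters("OCDF", k1, 0.1), cond_at(2)),
    numeric(1))
  expect_true(all(diff(gen_k1) > 0))
  gen_k2 <- vapply(seq(0.05, 1, length.out = 8), function(k2)
    congener_generation(kinetic_parameters("OCDF", 4.6e5, k2), cond_at(2)),
    numeric(1))
  expect_true(all(diff(gen_k2) < 0))  # faster decomposition, less output
})

test_that("reference congener selection takes the largest available share", {
  fx <- esp_example()
  marg <- profile_marginals(fx$profile)$congener
  expect_equal(select_reference_congener(marg), "OCDF")
  expect_equal(marg[["OCDF"]], 0.207, tolerance = 1e-12)
  expect_equal(select_reference_congener(marg, "2,3,7,8-TeCDF"),
               "2,3,7,8-TeCDF")
  # exact tie breaks to the earlier canonical index
  tied <- congener_profile(setNames(rep(1 / 17, 17), congener_names()))
  expect_equal(select_reference_congener(tied, c("OCDF", "2,3,7,8-TeCDF")),
               "2,3,7,8-TeCDF")
  expect_error(select_reference_congener(marg, character(0)), "available")
})

test_that("reference scale-up divides by the share", {
  expect_equal(total_from_reference(5, 0.207), 5 / 0.207)
  expect_equal(total_from_reference(3.3, 1), 3.3)
  expect_error(total_from_reference(1, 0), "positive")
  expect_error(total_from_reference(1, 1.2), "exceed")
})

test_that("influence factor configs: identity, linear, table lookup", {
  id <- influence_config("identity")
  f <- influence_factors(id, 0.007, 0.03, 1.2, 950)
  expect_equal(f, list(e_cl = 0.007, e_metal = 0.03, lambda_oxygen = 1.2))
  lin <- influence_config("linear",
                          reference = c(f_cl = 0.007, f_metal = 0.03,
                                        oxygen = 1.2))
  f1 <- influence_factors(lin, 0.007, 0.03, 1.2, 950)
  expect_equal(f1$e_cl, 1)
  f2 <- influence_factors(lin, 0.014, 0.03, 1.2, 950)
  expect_equal(f2$e_cl, 2 * f1$e_cl)
  tab <- influence_config("table", tables = list(
    e_cl = data.frame(x = c(0, 0.01, 0.02), value = c(0, 1, 1.5)),
    e_metal = data.frame(x = c(0, 0.05), value = c(0, 1)),
    lambda = data.frame(x = c(1, 2), value = c(1, 1.3))
  ))
  f3 <- influence_factors(tab, 0.005, 0.025, 1.5, 950)
  expect_equal(f3$e_cl, 0.5)    # hand lookup: halfway 0 -> 0.01
  expect_equal(f3$e_metal, 0.5)
  expect_equal(f3$lambda_oxygen, 1.15)
  expect_error(influence_config("table", tables = list()), "lookup")
  expect_error(influence_config("linear"), "reference")
})
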