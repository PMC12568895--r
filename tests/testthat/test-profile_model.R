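test_that("removal efficiency follows 1 - out/in and rejects zero inlet", {
  expect_equal(removal_efficiency(100, 25), 0.75)
  expect_equal(removal_efficiency(100, 261), -1.61)
  expect_error(removal_efficiency(0, 10), "positive")
  expect_error(removal_efficiency(100, -1), "nonnegative")
})

test_that("removal efficiency round-trips through the survival factor", {
  set.seed(8)
  eta <- stats::runif(50, -3, 1)
  c_in <- stats::rexp(50) + 0.1
  expect_equal(removal_efficiency(c_in, c_in * (1 - eta)), eta,
               tolerance = 1e-12)
})

test_that("propagation is the identity for zero or uniform efficiencies", {
  prof <- random_phase_profile(1)
  zero <- apcd_stage("none", matrix(0, 17, 2))
  expect_equal(unclass(propagate_profile(prof, zero))[, ],
               unclass(prof)[, ], tolerance = 1e-12)
  unif <- apcd_stage("unif", matrix(0.37, 17, 2))
  out <- propagate_profile(prof, unif)
  expect_equal(unclass(out)[, ], unclass(prof)[, ], tolerance = 1e-12)
  expect_equal(attr(out, "pass_through"), 1 - 0.37, tolerance = 1e-12)
})

test_that("complete removal zeroes an entry; total annihilation errors", {
  prof <- random_phase_profile(2)
  eta <- matrix(0, 17, 2)
  eta[3, 1] <- 1
  out <- propagate_profile(prof, apcd_stage("s", eta))
  expect_equal(unclass(out)[3, 1], 0)
  expect_error(propagate_profile(prof, apcd_stage("kill", matrix(1, 17, 2))),
               "pass-through")
})

test_that("propagation matches explicit mass bookkeeping and stays normalized", {
  for (seed in 1:10) {
    prof <- random_phase_profile(seed)
    stage <- random_stage(seed + 100)
    out <- propagate_profile(prof, stage)
    expect_equal(sum(out), 1, tolerance = 1e-12)
    # oracle: assign an arbitrary inlet concentration, remove mass per
    # entry, renormalize the surviving mass
    c_total <- 137.4
    mass_in <- unclass(prof) * c_total
    mass_out <- mass_in * (1 - stage$eta)
    expect_equal(unclass(out)[, ], (mass_out / sum(mass_out))[, ],
                 tolerance = 1e-12)
    # denominator equals 1 - aggregate efficiency exactly
    expect_equal(attr(out, "pass_through"),
                 1 - aggregate_efficiency(prof, stage, "all"),
                 tolerance = 1e-14)
    expect_equal(attr(out, "pass_through"), sum(mass_out) / c_total,
                 tolerance = 1e-12)
  }
})

test_that("collapsed 17-entry profiles propagate over 17 terms", {
  p <- congener_profile(setNames(rep(1 / 17, 17), congener_names()))
  eta <- setNames(stats::runif(17, -1, 0.5), congener_names())
  out <- propagate_profile(p, eta)
  expect_equal(sum(out), 1, tolerance = 1e-12)
  expect_equal(unclass(out), (1 - eta) / sum(1 - eta) , tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("aggregate efficiency reduces correctly for trivial stages", {
  prof <- random_phase_profile(3)
  expect_equal(aggregate_efficiency(prof, apcd_stage("z", matrix(0, 17, 2))),
               0)
  half <- apcd_stage("h", matrix(0.5, 17, 2))
  for (s in c("all", "gaseous", "particulate", "PCDD", "PCDF"))
    expect_equal(aggregate_efficiency(prof, half, s), 0.5)
})

test_that("marginals split a uniform profile evenly and renormalize", {
  unif <- phase_profile(matrix(1 / 34, 17, 2))
  m <- profile_marginals(unif)
  expect_equal(unname(m$phase), c(17 / 34, 17 / 34))
  expect_equal(sum(m$congener), 1)
  expect_equal(unname(unclass(m$congener)), rep(2 / 34, 17))
})

test_that("temperature repartitioning preserves totals and direction", {
  prof <- random_phase_profile(4)
  b <- default_vp_slopes()
  same <- repartition_by_temperature(prof, 234, 234, b)
  expect_equal(unclass(same)[, ], unclass(prof)[, ], tolerance = 1e-12)
  hot <- repartition_by_temperature(prof, 234, 284, b)
  expect_equal(rowSums(unclass(hot)), rowSums(unclass(prof)),
               tolerance = 1e-12)
  expect_true(all(unclass(hot)[, "gaseous"] >=
                  unclass(prof)[, "gaseous"] - 1e-12))
  cold <- repartition_by_temperature(prof, 284, 234, b)
  expect_true(all(unclass(cold)[, "gaseous"] <=
                  unclass(prof)[, "gaseous"] + 1e-12))
  expect_error(repartition_by_temperature(prof, 234, -300, b), "absolute")
})

test_that("two-congener repartitioning matches the closed-form equilibrium", {
  # all mass in two congeners with known gas shares and slopes
  m <- matrix(0, 17, 2, dimnames = list(congener_names(), phase_names()))
  m[1, ] <- c(0.3, 0.3)   # gas share 0.5
  m[17, ] <- c(0.1, 0.3)  # gas share 0.25
  prof <- phase_profile(m)
  b <- setNames(rep(4000, 17), congener_names())
  b[17] <- 6000
  t1 <- 234; t2 <- 284
  out <- repartition_by_temperature(prof, t1, t2, b)
  # hand algebra: odds' = odds * 10^(b (1/T1K - 1/T2K)); g' = odds'/(1+odds')
  r <- 10^(b * (1 / (t1 + 273.15) - 1 / (t2 + 273.15)))
  g1 <- (1 * r[[1]]) / (1 + 1 * r[[1]])        # odds were 0.5/0.5 = 1
  g17 <- ((1 / 3) * r[[17]]) / (1 + (1 / 3) * r[[17]])
  expect_equal(unclass(out)[1, "gaseous"], 0.6 * g1, tolerance = 1e-12)
  expect_equal(unclass(out)[17, "gaseous"], 0.4 * g17, tolerance = 1e-12)
})

test_that("chains compose propagation and accumulate pass-through", {
  prof <- random_phase_profile(5)
  expect_identical(chain_stages(prof, list())[[1]], prof)
  s1 <- apcd_stage("a", matrix(0.3, 17, 2))
  s2 <- apcd_stage("b", matrix(-0.5, 17, 2))
  out <- chain_stages(prof, list(s1, s2))
  expect_length(out, 3L)
  expect_equal(unclass(out[[3]])[, ], unclass(prof)[, ], tolerance = 1e-12)
  expect_equal(attr(out, "cumulative_pass_through"),
               c(0.7, 0.7 * 1.5), tolerance = 1e-12)
  # general composition: chain equals repeated propagate
  st <- list(random_stage(31), random_stage(32))
  out2 <- chain_stages(prof, st)
  step <- propagate_profile(propagate_profile(prof, st[[1]]), st[[2]])
  expect_equal(unclass(out2[[3]])[, ], unclass(step)[, ], tolerance = 1e-12)
})

test_that("profile correlation matches cor on canonical reordering", {
  x <- random_congener_masses(51)
  y <- random_congener_masses(52)
  expect_equal(profile_correlation(x, y), cor(x, y))
  expect_equal(profile_correlation(rev(x), y), cor(x, y))
})
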