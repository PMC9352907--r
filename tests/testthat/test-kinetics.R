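# Closed-form kinetics: FRET conversions, stationary occupancies,
# relaxation times, Kramers barriers, rate-table IO.

test_that("Forster conversions match hand-evaluated values and round-trip", {
  fc <- fret_constants()
  expect_equal(efficiency_from_distance(62.3, fc), 0.5)
  # 1/(1+(42/62.3)^6) and 1/(1+(80/62.3)^6), evaluated independently
  expect_equal(efficiency_from_distance(42, fc), 0.914, tolerance = 1e-3)
  expect_equal(efficiency_from_distance(80, fc), 0.182, tolerance = 3e-3)
  expect_error(efficiency_from_distance(-1, fc), "positive")

  expect_equal(efficiency_from_lifetime(3.2, 3.2), 0)
  expect_equal(efficiency_from_lifetime(0.25, 3.2), 1 - 0.25 / 3.2)
  expect_equal(efficiency_from_lifetime(0.91, 3.2), 0.7156, tolerance = 1e-4)
  expect_error(efficiency_from_lifetime(3.5, 3.2), "donor-only")

  expect_equal(distance_from_lifetime(1.6, fc), 62.3, tolerance = 1e-10)
  expect_equal(distance_from_lifetime(0.25, fc), 41.3, tolerance = 1e-2)
  expect_equal(distance_from_lifetime(2.75, fc), 84.2, tolerance = 0.05)
  expect_error(distance_from_lifetime(3.2, fc), "infinite")

  # inverse pair is the identity over the working distance range
  R <- seq(20, 120, by = 0.5)
  expect_equal(distance_from_efficiency(efficiency_from_distance(R, fc), fc),
               R, tolerance = 1e-10)
})

test_that("lifetime-derived distance preset reproduces the closed forms", {
  d <- pdi_distances("lifetime_derived")
  expect_equal(unname(round(d, 1)), c(84.2, 53.4, 41.3), tolerance = 1e-3)
  expect_equal(unname(pdi_distances("fixed")), c(80, 55, 42))
})

test_that("stationary distribution solves pi Q = 0 and matches Gillespie", {
  # symmetric two-state scheme
  s2 <- kinetic_scheme(matrix(c(0, 1, 1, 0), 2, 2), c(80, 42),
                       c(2.75, 0.25))
  expect_equal(unname(stationary_distribution(s2)), c(0.5, 0.5))

  for (sch in list(ox_scheme(), rd_scheme())) {
    p <- stationary_distribution(sch)
    expect_equal(sum(p), 1)
    expect_true(max(abs(p %*% generator_matrix(sch))) < 1e-12)
  }
  # published oxidized WT occupancies: 23/44/34 % after rounding
  expect_equal(unname(round(100 * stationary_distribution(ox_scheme()), 1)),
               c(22.6, 43.6, 33.8), tolerance = 1e-3)
  expect_equal(unname(round(100 * stationary_distribution(rd_scheme()), 1)),
               c(38.0, 51.2, 10.8), tolerance = 1e-3)

  # Monte-Carlo oracle on random schemes: long-trajectory time averages
  set.seed(11)
  for (r in 1:5) {
    k <- matrix(runif(9, 0.2, 5), 3, 3)
    sch <- kinetic_scheme(k, c(80, 55, 42), c(2.75, 0.91, 0.25))
    p <- stationary_distribution(sch)
    occ <- gillespie_occupancy(sch, total_ms = 2e4, seed = 100 + r)
    expect_equal(unname(p), occ, tolerance = 0.05)
  }

  # absorbing state is reported by name
  k_abs <- matrix(c(0, 1, 0, 0, 0, 1, 0, 0, 0), 3, 3, byrow = TRUE)
  k_abs[3, ] <- 0
  sch_abs <- kinetic_scheme(k_abs, c(80, 55, 42), c(2.75, 0.91, 0.25))
  expect_error(stationary_distribution(sch_abs), "C")
})

test_that("relaxation times match the closed form and the eigen route", {
  expect_equal(two_state_relaxation_time(4.50, 2.38), 145, tolerance = 0.005)
  expect_equal(two_state_relaxation_time(8.49, 6.28), 67.7, tolerance = 0.005)
  expect_equal(two_state_relaxation_time(1, 1), 500)
  expect_error(two_state_relaxation_time(0, 0), "zero")

  s2 <- kinetic_scheme(matrix(c(0, 4.50, 2.38, 0), 2, 2, byrow = TRUE),
                       c(80, 42), c(2.75, 0.25))
  expect_equal(relaxation_spectrum(s2), two_state_relaxation_time(4.50, 2.38),
               tolerance = 1e-12)

  sp3 <- relaxation_spectrum(ox_scheme())
  expect_length(sp3, 2)
  expect_true(all(is.finite(sp3)))
  expect_lt(sp3[1], 145)

  frozen <- kinetic_scheme(matrix(0, 3, 3), c(80, 55, 42),
                           c(2.75, 0.91, 0.25))
  expect_warning(sp <- relaxation_spectrum(frozen), "zero")
  expect_true(all(is.infinite(sp)))
})

test_that("Kramers barriers are monotone in rate and below 10 kBT for WT", {
  sch <- rd_scheme()
  fl <- kramers_barriers(sch, prefactor = 1e5)
  # k = A: zero barrier
  one <- kinetic_scheme(matrix(c(0, 100, 100, 0), 2, 2), c(80, 42),
                        c(2.75, 0.25))
  expect_equal(kramers_barriers(one, prefactor = 1e5)$barriers[1, 2], 0)
  # ln(1e5 / 110) for the slowest reduced WT rate
  expect_equal(fl$barriers["O2", "C"], log(1e5 / 110), tolerance = 1e-12)
  expect_equal(fl$barriers["O2", "C"], 6.81, tolerance = 1e-3)

  all_b <- c(kramers_barriers(ox_scheme())$barriers,
             kramers_barriers(rd_scheme())$barriers)
  expect_lt(max(all_b, na.rm = TRUE), 10)

  # monotonicity: slower rate, higher barrier
  ks <- sort(c(ox_scheme()$rates[ox_scheme()$rates > 0]))
  bs <- log(1e5 / (ks * 1000))
  expect_true(all(diff(bs) < 0))

  zero <- kinetic_scheme(matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE),
                         c(80, 42), c(2.75, 0.25))
  expect_message(fl0 <- kramers_barriers(zero), "infinite")
  expect_true(is.infinite(fl0$barriers[2, 1]))
})

test_that("cycle flux quantifies detailed-balance violation of fitted rates", {
  cf <- cycle_flux(ox_scheme())
  expect_equal(cf$forward, 4.50 * 0.78 * 0.15)
  expect_equal(cf$backward, 2.38 * 1.07 * 0.32)
  expect_false(isTRUE(all.equal(cf$log_ratio, 0)))
})

test_that("rate tables round-trip through CSV with the documented header", {
  sch <- ox_scheme()
  rp <- tempfile(fileext = ".csv")
  sp <- tempfile(fileext = ".csv")
  write_rate_table(sch, rp, sp)
  hdr <- readLines(rp, n = 1)
  expect_identical(hdr, "state_from,state_to,rate_ms^-1")
  back <- read_rate_table(rp, sp)
  expect_equal(back$rates, sch$rates)
  expect_equal(back$distances, sch$distances)
  expect_equal(back$lifetimes, sch$lifetimes)
})

test_that("the bundled rate table carries both redox states of all variants", {
  tab <- pdi_rate_table()
  expect_setequal(unique(tab$redox), c("oxidized", "reduced"))
  expect_length(unique(tab$variant), 6)
  expect_equal(nrow(tab), 2 * 6 * 10)
  # spot values
  expect_equal(pdi_scheme("reduced")$rates["O1", "O2"], 8.49)
  expect_equal(pdi_scheme("oxidized")$rates["C", "O2"], 1.07)
  expect_equal(unname(pdi_fractions("reduced")), c(39, 51, 9))
})

test_that("scheme validation rejects malformed inputs", {
  expect_error(kinetic_scheme(matrix(-1, 2, 2), c(80, 42), c(2.75, 0.25)),
               ">= 0")
  expect_error(kinetic_scheme(matrix(0, 2, 2), c(80, -1), c(2.75, 0.25)),
               "positive")
  expect_error(kinetic_scheme(matrix(0, 2, 2), c(80, 42), c(4.0, 0.25)),
               "tauD")
})
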