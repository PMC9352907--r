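# Dynamic PDA: binning, the Monte-Carlo forward model against analytic
# limits, and the global fitter.

test_that("bin_bursts cuts bursts into equal windows and applies thresholds", {
  sim <- rd_experiment()
  sp <- sim$spans[sim$spans$burst_id %in% sim$selected$burst_id, ]
  b25 <- bin_bursts(sim$stream, sp, 0.25, min_photons = 10)
  b100 <- bin_bursts(sim$stream, sp, 1.00, min_photons = 10)
  expect_true(all(b25$n >= 10))
  expect_true(all(b25$n_a <= b25$n))
  # photon conservation: windows cannot hold more photons than the bursts
  expect_lte(sum(b100$n), sum(sim$selected$n_dd + sim$selected$n_da))
  # a 9-photon window at min 10 is dropped
  b9 <- bin_bursts(sim$stream, sp, 0.25, min_photons = 11)
  expect_true(all(b9$n >= 11))
  expect_lt(nrow(b9), nrow(b25))
})

test_that("static one-state forward model equals the analytic binomial", {
  # all rates 0, sigma 0, no background, no corrections: PR at fixed N is
  # exactly Binomial(N, E)
  sch <- one_state_scheme(R = 55)
  E <- efficiency_from_distance(55, sch$constants)
  pm <- pda_model(sch, sigma = 0,
                  corrections = correction_set(DE = 0, Lk = 0, g = 1),
                  background_d = 0, background_a = 0, grid_E = 100)
  N <- 50L
  fw <- pda_forward(pm, 0.5, counts = N, n_samples = 1e5, seed = 3)
  # analytic binomial folded onto the same PR grid (same floor convention)
  p_bin <- dbinom(0:N, N, E)
  grid_idx <- pmin(floor((0:N) / N * 100) + 1L, 100L)
  p_grid <- tapply(p_bin, grid_idx, sum)
  expect_pr <- rep(0, 100)
  expect_pr[as.integer(names(p_grid))] <- p_grid
  tv <- 0.5 * sum(abs(fw$prob - expect_pr))
  expect_lt(tv, 0.01)
})

test_that("frozen three-state mixture shows three modes at the state PRs", {
  sch <- ox_scheme()
  frozen <- kinetic_scheme(sch$rates * 1e-9, sch$distances, sch$lifetimes,
                           sch$labels, sch$constants)
  pm <- pda_model(frozen, sigma = 0,
                  corrections = correction_set(DE = 0, Lk = 0, g = 1),
                  background_d = 0, background_a = 0)
  fw <- pda_forward(pm, 0.5, counts = 200L, n_samples = 5e4, seed = 4,
                    init = stationary_distribution(sch))
  E <- efficiency_from_distance(sch$distances, sch$constants)
  mids <- (fw$breaks[-1] + fw$breaks[-101]) / 2
  for (e in E) {
    near <- abs(mids - e) < 0.05
    far <- abs(mids - e) > 0.1 & abs(mids - e) < 0.2
    expect_gt(max(fw$prob[near]), max(fw$prob[far]))
  }
})

test_that("fast exchange collapses to a single mode at the weighted mean", {
  k <- matrix(c(0, 50, 50, 0), 2, 2)
  sch <- kinetic_scheme(k, c(80, 42), c(2.75, 0.25))
  pm <- pda_model(sch, sigma = 0,
                  corrections = correction_set(DE = 0, Lk = 0, g = 1),
                  background_d = 0, background_a = 0)
  fw <- pda_forward(pm, 1, counts = 100L, n_samples = 5e4, seed = 5)
  E <- efficiency_from_distance(c(80, 42), sch$constants)
  # intensity-weighted mean PR (equal occupancy, donor-rate weighting)
  w <- (1 - E)
  # with identity corrections PR per state equals E; fast exchange averages
  # the acceptor rate over the dwell -> single mode near mean(E)
  mids <- (fw$breaks[-1] + fw$breaks[-101]) / 2
  mode_pr <- mids[which.max(fw$prob)]
  expect_equal(mode_pr, mean(E), tolerance = 0.05)
  # unimodal: negligible mass at the pure-state efficiencies
  expect_lt(fw$prob[findInterval(E[1], fw$breaks)], 0.005)
  expect_lt(fw$prob[findInterval(E[2], fw$breaks)] /
              max(fw$prob), 0.2)
})

test_that("bin-time broadening of dynamic mixing is monotone", {
  # two-state scheme at moderate exchange: mass between the pure modes
  # grows with bin time
  k <- matrix(c(0, 1.5, 1.5, 0), 2, 2)
  sch <- kinetic_scheme(k, c(80, 42), c(2.75, 0.25))
  pm <- pda_model(sch, sigma = 0,
                  corrections = correction_set(DE = 0, Lk = 0, g = 1),
                  background_d = 0, background_a = 0)
  E <- sort(efficiency_from_distance(c(80, 42), sch$constants))
  between <- function(bin_ms) {
    fw <- pda_forward(pm, bin_ms, counts = 150L, n_samples = 4e4, seed = 6)
    mids <- (fw$breaks[-1] + fw$breaks[-101]) / 2
    sum(fw$prob[mids > E[1] + 0.12 & mids < E[2] - 0.12])
  }
  frac <- vapply(c(0.25, 0.5, 1), between, numeric(1))
  expect_true(all(diff(frac) > -0.02))
  expect_gt(frac[3], frac[1])
})

test_that("the global fitter enforces its contract", {
  sim <- rd_experiment()
  sp <- sim$spans[sim$spans$burst_id %in% sim$selected$burst_id, ]
  pm <- pda_model(rd_scheme(), bin_times_ms = c(0.5))
  h1 <- pda_prepare(sim$stream, sp, pm)
  expect_error(pda_fit_global(h1, pm), ">= 2 bin times")
  pm2 <- pda_model(rd_scheme(), bin_times_ms = c(0.5, 1))
  h2 <- list(list(counts = rep(0, 100), n_library = integer()),
             list(counts = rep(0, 100), n_library = integer()))
  expect_error(pda_fit_global(h2, pm2), "empty")
})

test_that("rates are recovered from self-generated histograms", {
  # generative round-trip: histograms produced by the forward model at the
  # oxidized WT rates across all four bin times, refit from uniform
  # initial rates of 1 ms^-1; each rate within 25% or 0.3 ms^-1
  sch <- ox_scheme()
  pm <- pda_model(sch)
  set.seed(31)
  lib <- as.integer(round(rexp(4000, 1 / 40)) + 12)
  nwin <- c(15000, 6000, 3000, 1800)
  hs <- lapply(seq_along(pm$bin_times_ms), function(i) {
    # high-precision forward draw (independent seeds) as pseudo-data
    fw <- pda_forward(pm, pm$bin_times_ms[i], counts = lib,
                      n_samples = 1e5, seed = 777 + i)
    list(counts = round(fw$prob * nwin[i]), n_library = lib)
  })
  fit <- pda_fit_global(hs, pm, initial_rates = 1, n_samples = 2e4,
                        seed = 7, maxit = 300)
  err <- abs(fit$rates - sch$rates)
  rel <- err / pmax(sch$rates, 1e-9)
  ok <- (rel < 0.25) | (err < 0.3)
  expect_true(all(ok[row(ok) != col(ok)]))
})

test_that("restart protocol averages three determinations and flags issues", {
  sim <- rd_experiment()
  sp <- sim$spans[sim$spans$burst_id %in% sim$selected$burst_id, ]
  pm <- pda_model(rd_scheme(), bin_times_ms = c(0.5, 1))
  hs <- pda_prepare(sim$stream, sp, pm)
  rob <- pda_robustness(hs, pm, n_samples = 2e4, seed = 9, maxit = 300)
  expect_length(rob$fits, 3)
  expect_equal(dim(rob$rates_sd), c(3, 3))
  expect_equal(sum(rob$fractions_mean), 100, tolerance = 0.5)
  # well-conditioned data: restart scatter below the mean for the dominant
  # O1<->O2 rates
  expect_lt(rob$rates_sd[1, 2], pmax(rob$rates_mean[1, 2], 0.1))

  # flat uninformative histograms flag multi-modal or hit the bounds
  flat <- lapply(1:2, function(i)
    list(counts = rep(20, 100), n_library = rep(30L, 200)))
  rob_flat <- suppressWarnings(
    pda_robustness(flat, pm, n_samples = 1e4, seed = 10, maxit = 150))
  expect_true(rob_flat$multi_modal ||
                any(vapply(rob_flat$fits, function(f) f$at_bounds,
                           logical(1))))
})
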