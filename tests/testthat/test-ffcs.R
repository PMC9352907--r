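# Species-filtered FCS: filter construction, correlators, global fit.

test_that("species filters are complete and unbiased on a static mixture", {
  # static two-species mixture (no exchange): the extracted species
  # patterns are pure, so filtered counts must recover the ground-truth
  # per-species photon counts
  k0 <- matrix(0, 2, 2)
  sch <- kinetic_scheme(k0, c(80, 55), c(2.75, 0.91), c("O1", "O2"))
  mod <- molecule_model(sch, sigma = 0, contaminant_fractions = c(0, 0))
  acq <- acquisition_config(duration_s = 40)
  st <- simulate_experiment(mod, acq, n_bursts = 4000, seed = 45)
  spans <- apbs_search(st)
  sel <- select_fret_bursts(score_bursts(st, spans))
  # selection windows symmetric around the species efficiencies (0.18 and
  # 0.68) and wide against shot noise, so conditioning on measured E does
  # not skew the extracted microtime patterns
  filt <- build_filters(st, sel, spans,
                        species_windows = list(S1 = c(0.08, 0.28),
                                               S2 = c(0.58, 0.78)))

  # completeness: weights over species+background sum to 1 in every used bin
  cs <- colSums(filt$weights[, filt$used_bins])
  expect_lt(max(abs(cs - 1)), 1e-10)

  # unbiasedness on the calibration mixture: applying the filters to the
  # burst-selected photons recovers each species' in-burst photon count
  idx <- sequence(spans$i_end - spans$i_start + 1L, from = spans$i_start)
  sub <- st[idx, ]
  for (a in c("pie_period_ns", "microtime_resolution_ns", "irf_mean_ns",
              "irf_sigma_ns", "duration_s"))
    attr(sub, a) <- attr(st, a)
  class(sub) <- c("photon_stream", "data.frame")
  dex <- microtime_ns(sub) < 25
  truth <- c(sum(dex & sub$state == 1), sum(dex & sub$state == 2))
  n_hat <- filtered_counts(sub, filt)
  expect_equal(unname(n_hat[1] / truth[1]), 1, tolerance = 0.02)
  expect_equal(unname(n_hat[2] / truth[2]), 1, tolerance = 0.02)
})

test_that("identical microtime patterns are rejected as collinear", {
  sim <- ffcs_experiment()
  # same window twice -> identical patterns
  expect_error(
    build_filters(sim$stream, sim$sel, sim$spans,
                  species_windows = list(A = c(0.6, 0.75),
                                         B = c(0.6, 0.75))),
    "collinear")
})

test_that("uncorrelated background correlates to zero", {
  sch <- ffcs_experiment()$scheme
  mod <- molecule_model(sch)
  acq <- acquisition_config(duration_s = 20)
  bg <- simulate_experiment(mod, acq, n_bursts = 0, seed = 51)
  # constant filter weights: plain intensity correlation of Poisson noise
  w <- rep(1, nrow(bg))
  t_s <- photon_times(bg)
  x <- fretdyn:::cpp_bin_weights(t_s, w, 2e-6, 0, as.integer(20 / 2e-6))
  g <- fretdyn:::cpp_multitau(x, x, 2e-6, 16, 10)
  # flat at zero within the shot-noise scatter of a 20 s record
  expect_lt(abs(mean(g$G[g$lag_s > 1e-5])), 0.02)
  expect_lt(max(abs(g$G[g$lag_s > 1e-5])), 0.5)
})

test_that("static mixtures show no relaxation term beyond error", {
  # two static species, no exchange: cross-correlation carries the
  # diffusion term only, and the fitted kinetic amplitudes are tiny
  k0 <- matrix(0, 2, 2)
  sch <- kinetic_scheme(k0, c(80, 55), c(2.75, 0.91), c("O1", "O2"))
  mod <- molecule_model(sch, contaminant_fractions = c(0, 0))
  acq <- acquisition_config(duration_s = 40)
  st <- simulate_experiment(mod, acq, n_bursts = 4000, seed = 61)
  spans <- apbs_search(st)
  sel <- select_fret_bursts(score_bursts(st, spans))
  filt <- build_filters(st, sel, spans)
  curves <- correlate_filtered(st, filt)
  fit <- suppressWarnings(fit_fcs_global(curves))
  # CCF relaxation amplitude consistent with zero at 3 sigma, or the fit
  # flags unidentifiability
  ccf_sig <- fit$amplitude_significance[c("sCCF_12", "sCCF_21")]
  expect_true(fit$unidentifiable || all(ccf_sig < 3 | !is.finite(ccf_sig)))
})

test_that("two-state exchange yields bell-shaped sCCFs and recovers tau_R", {
  sim <- ffcs_experiment()
  filt <- build_filters(sim$stream, sim$sel, sim$spans)
  curves <- correlate_filtered(sim$stream, filt)
  fit <- fit_fcs_global(curves)
  # truth: 1/(8.49 + 6.28) ms = 67.7 us
  expect_equal(fit$tau_R_us, 67.7, tolerance = 0.20 * 67.7)
  # anti-correlated kinetic term in the cross-correlations, significant
  ccf_A <- fit$amplitudes[c("sCCF_12", "sCCF_21")]
  ccf_sig <- fit$amplitude_significance[c("sCCF_12", "sCCF_21")]
  expect_true(all(ccf_A < 0))
  expect_true(all(ccf_sig > 3))
  # bell shape: CCF rises from short lags toward the diffusion shoulder
  cc <- curves$sCCF_12
  early <- mean(cc$G[cc$lag_s < 1e-5])
  shoulder <- mean(cc$G[cc$lag_s > 2e-4 & cc$lag_s < 6e-4])
  expect_gt(shoulder, early)
  # time-reversible two-state scheme: the two CCFs agree within errors
  m <- min(nrow(curves$sCCF_12), nrow(curves$sCCF_21))
  d <- abs(curves$sCCF_12$G[1:m] - curves$sCCF_21$G[1:m])
  e <- sqrt(curves$sCCF_12$err[1:m]^2 + curves$sCCF_21$err[1:m]^2)
  expect_lt(median(d / e, na.rm = TRUE), 3)
})

test_that("model-generated curves round-trip through the global fit", {
  lag <- exp(seq(log(4e-6), log(5e-2), length.out = 60))
  gd <- 1 / ((1 + lag / 469e-6) * sqrt(1 + lag / (4.6^2 * 469e-6)))
  tauR <- 100e-6
  kinds <- c("sACF_1", "sACF_2", "sCCF_12", "sCCF_21")
  A <- c(0.4, 0.35, -0.45, -0.45)
  G0 <- c(0.05, 0.04, 0.03, 0.03)
  set.seed(71)
  curves <- lapply(seq_along(kinds), function(i) {
    G <- G0[i] * gd * (1 + A[i] * exp(-lag / tauR))
    noise <- 0.02 * G0[i]
    data.frame(lag_s = lag, G = G + rnorm(length(lag), 0, noise),
               err = rep(noise, length(lag)), kind = kinds[i])
  })
  names(curves) <- kinds
  fit <- fit_fcs_global(curves)
  expect_equal(fit$tau_R_us, 100, tolerance = 5)
  expect_equal(unname(fit$amplitudes), A, tolerance = 0.1)
  expect_lt(abs(fit$chi2_reduced - 1), 0.5)
})
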