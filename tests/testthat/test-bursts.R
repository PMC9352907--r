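# Burst search, corrected E/S, the quality filters and the FRET histogram.

test_that("apbs_search returns sorted disjoint spans and handles edge cases", {
  sim <- rd_experiment()
  spans <- sim$spans
  expect_gt(nrow(spans), 200)
  expect_true(all(diff(spans$i_start) > 0))
  expect_true(all(spans$i_start[-1] > spans$i_end[-nrow(spans)]))
  expect_true(all(spans$counts > 40))

  empty <- simulate_experiment(molecule_model(rd_scheme()),
                               acquisition_config(duration_s = 0.01),
                               n_bursts = 0, seed = 1)
  expect_equal(nrow(apbs_search(empty[0, ])), 0)

  # property: disjoint sorted spans on random sparse streams
  for (s in 1:3) {
    stx <- simulate_experiment(molecule_model(ox_scheme()),
                               acquisition_config(duration_s = 2),
                               n_bursts = 60, seed = 200 + s)
    sp <- apbs_search(stx)
    if (nrow(sp) > 1) {
      expect_true(all(sp$i_start[-1] > sp$i_end[-nrow(sp)]))
      expect_true(!is.unsorted(sp$t_start_s))
    }
  }
})

test_that("planted bright bursts are recovered with high recall", {
  # recall among planted transits that actually yielded enough photons
  sim <- rd_experiment()
  st <- sim$stream
  spans <- sim$spans
  per_mol <- tabulate(st$molecule[st$molecule > 0], attr(st, "n_bursts"))
  plantable <- which(per_mol > 44)
  idx <- sequence(spans$i_end - spans$i_start + 1L, from = spans$i_start)
  found_mol <- unique(st$molecule[idx])
  recall <- mean(plantable %in% found_mol)
  expect_gte(recall, 0.98)
})

test_that("a 40-count event is excluded (threshold is strict)", {
  # two synthetic photon clusters over silence: 40 and 42 photons
  acq <- acquisition_config(duration_s = 1)
  t40 <- seq(0.1, 0.1 + 0.39e-3, length.out = 40)
  t42 <- seq(0.5, 0.5 + 0.41e-3, length.out = 42)
  t <- c(t40, t42)
  df <- data.frame(macrotime = floor(t * 1e9 / 50),
                   microtime = rep(10L, length(t)),
                   detector = rep(1L, length(t)),
                   molecule = 0L, state = 0L, species = 0L)
  st <- structure(df, class = c("photon_stream", "data.frame"),
                  pie_period_ns = 50, microtime_resolution_ns = 0.05,
                  irf_mean_ns = 1.5, irf_sigma_ns = 0.106, duration_s = 1)
  sp <- apbs_search(st, window_ms = 0.5, min_counts = 40)
  expect_equal(nrow(sp), 1)
  expect_equal(sp$counts, 42)
})

test_that("compute_es matches the hand-evaluated correction formulas", {
  id <- correction_set(DE = 0, Lk = 0, g = 1)
  r <- compute_es(50, 50, 50, id)
  expect_equal(r$E, 0.5)
  expect_equal(r$S, 2 / 3, tolerance = 1e-12)

  co <- correction_set(DE = 0.05, Lk = 0.08, g = 0.85)
  r2 <- compute_es(50, 50, 50, co)
  # F_A = 50 - 0.08*50 - 0.05*50 = 43.5; E = 43.5/(43.5 + 42.5)
  expect_equal(r2$E, 43.5 / 86, tolerance = 1e-12)
  expect_equal(r2$S, 86 / 136, tolerance = 1e-12)
  expect_equal(round(r2$E, 3), 0.506)
  expect_equal(round(r2$S, 3), 0.632)

  # donor-only: S ~ 1; zero denominator flags, does not drop
  expect_gt(compute_es(100, 8, 0, co)$S, 0.9)
  z <- compute_es(0, 0, 0, co)
  expect_false(z$valid)
  expect_true(is.na(z$E))
})

test_that("ALEX-2CDE separates interleaved from bleached bursts", {
  mk_stream <- function(td, ta) {
    t <- sort(c(td, ta))
    slotA <- t %in% ta
    df <- data.frame(macrotime = floor(t * 1e9 / 50),
                     microtime = ifelse(slotA, 700L, 10L),
                     detector = ifelse(slotA, 3L, 1L),
                     molecule = 1L, state = 0L, species = 0L)
    structure(df, class = c("photon_stream", "data.frame"),
              pie_period_ns = 50, microtime_resolution_ns = 0.05,
              irf_mean_ns = 1.5, irf_sigma_ns = 0.106, duration_s = 1)
  }
  n <- 200
  # uniformly interleaved
  st1 <- mk_stream(seq(0, 1e-3, length.out = n),
                   seq(0, 1e-3, length.out = n) + 2.6e-6)
  sp1 <- data.frame(burst_id = 1L, i_start = 1L, i_end = 2L * n,
                    t_start_s = 0, duration_ms = 1, counts = 2L * n)
  expect_lt(alex_2cde(st1, sp1), 14)
  # acceptor-excitation photons all precede donor-excitation photons
  st2 <- mk_stream(seq(0.5e-3, 1e-3, length.out = n),
                   seq(0, 0.49e-3, length.out = n))
  expect_gt(alex_2cde(st2, sp1), 14)
  # single-slot burst is infinite (filtered)
  st3 <- mk_stream(seq(0, 1e-3, length.out = n), numeric())
  sp3 <- sp1; sp3$i_end <- n
  expect_true(is.infinite(alex_2cde(st3, sp3)))
})

test_that("|TDX-TAA| is 0 for co-centred channels, 0.5 for half-split", {
  mk <- function(td, ta) {
    t <- sort(c(td, ta))
    slotA <- t %in% ta
    df <- data.frame(macrotime = floor(t * 1e9 / 50),
                     microtime = ifelse(slotA, 700L, 10L),
                     detector = ifelse(slotA, 3L, 1L),
                     molecule = 1L, state = 0L, species = 0L)
    structure(df, class = c("photon_stream", "data.frame"),
              pie_period_ns = 50, microtime_resolution_ns = 0.05,
              irf_mean_ns = 1.5, irf_sigma_ns = 0.106, duration_s = 1)
  }
  n <- 400
  sp <- data.frame(burst_id = 1L, i_start = 1L, i_end = 2L * n,
                   t_start_s = 0, duration_ms = 1, counts = 2L * n)
  even <- mk(seq(0, 1e-3, length.out = n),
             seq(0, 1e-3, length.out = n) + 1e-6)
  expect_lt(tdx_taa_filter(even, sp), 0.02)
  # acceptor photons in the first half, donor in the second: means at 1/4
  # and 3/4 of the duration
  split <- mk(seq(0.5e-3, 1e-3, length.out = n),
              seq(0, 0.5e-3, length.out = n))
  expect_equal(tdx_taa_filter(split, sp), 0.5, tolerance = 0.01)
})

test_that("filter cascade removes contaminants, is conjunctive and idempotent", {
  sim <- rd_experiment()
  sel <- sim$selected
  # ground-truth species of each selected burst
  st <- sim$stream
  sp_sel <- sim$spans[sim$spans$burst_id %in% sel$burst_id, ]
  idx <- sequence(sp_sel$i_end - sp_sel$i_start + 1L,
                  from = sp_sel$i_start)
  grp <- rep.int(seq_len(nrow(sp_sel)), sp_sel$i_end - sp_sel$i_start + 1L)
  main_species <- vapply(split(st$species[idx], grp), function(x) {
    x <- x[x > 0]
    if (!length(x)) return(0L)
    as.integer(names(which.max(table(x))))
  }, integer(1))
  contam <- mean(main_species != 1)
  expect_lt(contam, 0.01)

  # S = 0.8 burst removed
  fake <- sel[1, ]; fake$S <- 0.8
  expect_equal(nrow(select_fret_bursts(rbind(sel, fake))), nrow(sel))
  # idempotence / order invariance of the conjunction
  again <- select_fret_bursts(sel)
  expect_equal(nrow(again), nrow(sel))
  expect_equal(sum(attr(again, "removed")), 0)
})

test_that("per-state burst E matches the Forster prediction on clean data", {
  # truth corrections equal analysis corrections: per-state mean burst E
  # for >=100-photon pure bursts within 0.02 of E(R_state)
  sim <- rd_experiment()
  st <- sim$stream
  sel <- sim$selected
  sp_sel <- sim$spans[sim$spans$burst_id %in% sel$burst_id, ]
  idx_list <- split(
    sequence(sp_sel$i_end - sp_sel$i_start + 1L, from = sp_sel$i_start),
    rep.int(seq_len(nrow(sp_sel)), sp_sel$i_end - sp_sel$i_start + 1L))
  sch <- sim$model$scheme
  # expected burst E includes the sigma-broadened distance distribution
  # (Jensen correction relative to E at the mean distance)
  Etheory <- vapply(seq_along(sch$distances), function(s) {
    g <- seq(-5, 5, length.out = 201)
    R <- sch$distances[s] * (1 + sim$model$sigma * g)
    w <- dnorm(g)
    sum(w * efficiency_from_distance(pmax(R, 1), sch$constants)) / sum(w)
  }, numeric(1))
  for (s in 1:3) {
    pure <- vapply(idx_list, function(ii) {
      stt <- st$state[ii]
      sum(stt > 0) > 0 && mean(stt[stt > 0] == s) > 0.97
    }, logical(1))
    big <- sel$n_dd + sel$n_da + sel$n_aa >= 100
    use <- pure & big
    if (sum(use) >= 20) {
      expect_lt(abs(mean(sel$E[use]) - Etheory[s]), 0.02,
                label = paste("state", s, "mean E deviation"))
    }
  }
})

test_that("fret_histogram summarises burst efficiencies", {
  sim <- rd_experiment()
  h <- fret_histogram(sim$selected)
  expect_equal(sum(h$counts), h$n)
  expect_true(h$sd > 0.1)  # dynamic mixture spans the state means
  expect_error(fret_histogram(sim$selected[0, ]), "no bursts")
})
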