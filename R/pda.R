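# Dynamic photon distribution analysis: Monte-Carlo forward model of
# proximity-ratio histograms under multi-state kinetics, and a global fitter
# of the exchange rates across several bin times.
#
# PDA operates on the raw proximity ratio PR = N_DA / (N_DA + N_DD) of
# donor-excitation photons per time bin; corrections, distance broadening
# and background are folded into the forward model so the binomial photon
# statistics stay exact.

#' PDA model specification
#'
#' @param scheme A [kinetic_scheme()]; distances and sigma are fixed inputs
#'   of the fit, only the rates are free parameters.
#' @param sigma Fractional width of the per-state distance distribution.
#' @param corrections A [correction_set()] folded into the forward model.
#' @param brightness Donor-excitation detected counts/ms at E = 0 (used to
#'   weight state dwell times by detected intensity).
#' @param background_d,background_a Donor / acceptor channel background
#'   falling inside the donor-excitation window, counts/ms (half of the
#'   total channel background under 50:50 pulsed interleaving).
#' @param bin_times_ms Bin times of the global fit.
#' @param grid_E Number of proximity-ratio histogram bins.
#' @param min_photons Minimum donor-excitation photons per retained bin.
#' @param dark_fraction Optional fraction of bins whose acceptor is in a
#'   dark, non-FRET state (adds a leakage-only low-PR component to the
#'   forward model). Off by default.
#' @param couple_counts If `TRUE`, the photon count drawn from the library
#'   is rescaled by the sampled path's relative detected intensity, so
#'   high-FRET dwells (which detect fewer donor-window photons when the
#'   detection factor g < 1) carry correspondingly smaller counts — the
#'   correlation the plain histogram-library draw ignores.
#' @return Object of class `pda_model`.
#' @export
pda_model <- function(scheme, sigma = 0.045, corrections = correction_set(),
                      brightness = 200, background_d = 0.5,
                      background_a = 0.35,
                      bin_times_ms = c(0.25, 0.5, 0.75, 1),
                      grid_E = 100, min_photons = 10, dark_fraction = 0,
                      couple_counts = TRUE) {
  stopifnot(inherits(scheme, "kinetic_scheme"), sigma >= 0,
            all(bin_times_ms > 0), grid_E >= 10,
            dark_fraction >= 0, dark_fraction < 1)
  structure(list(scheme = scheme, sigma = sigma, corrections = corrections,
                 brightness = brightness, background_d = background_d,
                 background_a = background_a, bin_times_ms = bin_times_ms,
                 grid_E = grid_E, min_photons = min_photons,
                 dark_fraction = dark_fraction,
                 couple_counts = couple_counts),
            class = "pda_model")
}

#' Cut burst photon trains into PDA time bins
#'
#' Slices each burst into consecutive windows of `bin_time_ms` (incomplete
#' trailing windows are discarded so every retained bin has the same
#' duration), counts donor-excitation photons per window, and drops windows
#' below the photon threshold.
#'
#' @param stream A `photon_stream`.
#' @param spans Burst spans from [apbs_search()] (typically restricted to
#'   the bursts that survived [select_fret_bursts()]).
#' @param bin_time_ms Window length in ms.
#' @param min_photons Minimum donor-excitation photons per retained window.
#' @return Data frame with columns `n` (donor-excitation photons) and `n_a`
#'   (those detected in the acceptor channel); `pr = n_a/n` is the proximity
#'   ratio.
#' @export
bin_bursts <- function(stream, spans, bin_time_ms, min_photons = 10) {
  if (!nrow(spans)) return(data.frame(n = integer(), n_a = integer()))
  t <- photon_times(stream)
  slot <- excitation_slot(stream)
  det <- stream$detector
  idx <- rep.int(seq_len(nrow(spans)), spans$i_end - spans$i_start + 1L)
  ph <- sequence(spans$i_end - spans$i_start + 1L, from = spans$i_start)
  dex <- slot[ph] == 1L
  win <- floor((t[ph] - spans$t_start_s[idx]) / (bin_time_ms * 1e-3))
  n_full <- floor(spans$duration_ms[idx] / bin_time_ms)
  keep <- dex & win < n_full
  key <- paste(idx[keep], win[keep])
  n <- tapply(rep(1L, sum(keep)), key, sum)
  na <- tapply(det[ph][keep] %in% c(3L, 4L), key, sum)
  out <- data.frame(n = as.integer(n), n_a = as.integer(na[names(n)]))
  out <- out[out$n >= min_photons, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Proximity-ratio histogram
#'
#' @param bins Output of [bin_bursts()] (or any data frame with `n`, `n_a`).
#' @param grid_E Number of PR bins over `[0, 1]`.
#' @return List with `counts` (length `grid_E`), `breaks`, `n_windows`.
#' @export
pr_histogram <- function(bins, grid_E = 100) {
  pr <- bins$n_a / bins$n
  breaks <- seq(0, 1, length.out = grid_E + 1L)
  b <- pmin(pmax(findInterval(pr, breaks, rightmost.closed = TRUE), 1L),
            grid_E)
  list(counts = tabulate(b, nbins = grid_E), breaks = breaks,
       n_windows = length(pr))
}

#' Monte-Carlo PDA forward model
#'
#' For each sample: draw a photon count from the supplied bin-count library,
#' draw one sigma-broadened distance per state, run a state path over the
#' bin, and form the intensity-weighted mean proximity ratio (corrections
#' and background folded in). The exact binomial shot-noise distribution of
#' the acceptor count is then accumulated onto the PR grid
#' (Rao-Blackwellized estimate: only the path and distance draws are
#' stochastic), which makes the histogram smooth enough for chi-squared
#' fitting at moderate sample counts.
#'
#' @param model A [pda_model()].
#' @param bin_time_ms Bin time in ms.
#' @param counts Integer vector: the empirical photon-count library for this
#'   bin time (sampled with replacement).
#' @param n_samples Monte-Carlo sample count (>= 1e4 recommended).
#' @param seed Integer seed making the histogram deterministic.
#' @param rates Optional off-diagonal rate matrix (ms^-1) overriding the
#'   scheme's (used by the fitter).
#' @param init Initial-state probabilities; default stationary for the used
#'   rates.
#' @return List as in [pr_histogram()] plus `prob` (normalized histogram).
#' @export
pda_forward <- function(model, bin_time_ms, counts, n_samples = 1e5,
                        seed = 1, rates = NULL, init = NULL) {
  if (n_samples < 1e4)
    warning("fewer than 1e4 forward samples; histogram will be noisy")
  sch <- model$scheme
  if (is.null(rates)) rates <- sch$rates
  if (is.null(init)) {
    tmp <- kinetic_scheme(rates, sch$distances, sch$lifetimes,
                          sch$labels, sch$constants)
    init <- tryCatch(stationary_distribution(tmp),
                     error = function(e)
                       rep(1 / nrow(rates), nrow(rates)))
  }
  co <- model$corrections
  .with_seed(seed, {
    N <- if (length(counts) == 1L) rep.int(as.integer(counts), n_samples)
         else sample(counts, n_samples, replace = TRUE)
    n_dark <- round(model$dark_fraction * n_samples)
    hist <- cpp_pda_forward_hist(rates, as.numeric(init), bin_time_ms,
                                 as.integer(N[seq_len(n_samples - n_dark)]),
                                 as.numeric(sch$distances),
                                 sch$constants$R0, model$sigma, co$g,
                                 co$Lk, co$DE, model$brightness,
                                 model$background_d, model$background_a,
                                 as.integer(model$grid_E),
                                 isTRUE(model$couple_counts))
    if (n_dark > 0) {
      # dark-acceptor bins: donor-only photophysics (leakage + background
      # only in the acceptor channel)
      hist <- hist + cpp_pda_forward_hist(
        matrix(0, 1, 1), 1, bin_time_ms,
        as.integer(N[seq.int(n_samples - n_dark + 1L, n_samples)]),
        1e6, sch$constants$R0, 0, co$g, co$Lk, 0, model$brightness,
        model$background_d, model$background_a, as.integer(model$grid_E),
        isTRUE(model$couple_counts))
    }
    list(counts = hist, breaks = seq(0, 1, length.out = model$grid_E + 1L),
         n_windows = n_samples, prob = hist / sum(hist))
  })
}

# Pearson chi2 between an observed histogram and forward probabilities.
# Expected counts are floored at half a count: isolated outlier windows in
# bins the model leaves empty (filter leakage, coincident molecules) would
# otherwise dominate the objective and reward spurious tail-fattening
# exchange rates.
.pda_chi2 <- function(obs_counts, prob, n_samples) {
  Ntot <- sum(obs_counts)
  p <- pmax(prob, 0.5 / max(Ntot, 1), 0.5 / n_samples)
  p <- p / sum(p)
  expd <- Ntot * p
  use <- obs_counts > 0 | expd > 1e-3
  sum((obs_counts[use] - expd[use])^2 / expd[use])
}

#' Global dynamic-PDA fit across bin times
#'
#' Minimizes the summed Pearson chi-squared between measured proximity-ratio
#' histograms at several bin times and the Monte-Carlo forward model, over
#' the off-diagonal exchange rates (distances and sigma stay fixed).
#' Derivative-free simplex on log-rates; the forward seed is fixed per
#' evaluation so the objective is deterministic during optimization. Initial
#' state probabilities are tied to the stationary distribution of the
#' candidate rates (set `free_fractions = TRUE` to float them).
#'
#' @param histograms Named list (one per bin time) with elements `counts`
#'   (PR histogram) and `n_library` (bin photon-count library), e.g. from
#'   [pda_prepare()].
#' @param model A [pda_model()].
#' @param initial_rates Initial value for every off-diagonal rate (ms^-1),
#'   scalar or full matrix.
#' @param bounds Rate bounds in ms^-1.
#' @param n_samples Forward-model samples per histogram evaluation.
#' @param seed Seed for the deterministic forward draws.
#' @param free_fractions If `TRUE`, the initial-bin state probabilities are
#'   fitted independently of the rates.
#' @param maxit Simplex iteration budget.
#' @return Object of class `pda_fit`: `rates` (matrix, ms^-1), `fractions`
#'   (percent), `chi2_per_bin`, `chi2_global` (per degree of freedom),
#'   `convergence`, `at_bounds`, `free_fractions`.
#' @export
pda_fit_global <- function(histograms, model, initial_rates = 1,
                           bounds = c(0, 10), n_samples = 3e4, seed = 1,
                           free_fractions = FALSE, maxit = 400) {
  if (length(histograms) < 2L)
    stop("global PDA requires histograms at >= 2 bin times")
  if (all(vapply(histograms, function(h) sum(h$counts) == 0, logical(1))))
    stop("all histograms are empty")
  sch <- model$scheme
  ns <- length(sch$labels)
  off <- which(row(matrix(0, ns, ns)) != col(matrix(0, ns, ns)))
  k0 <- if (length(initial_rates) == 1L)
    matrix(initial_rates, ns, ns) else as.matrix(initial_rates)
  npar_r <- length(off)
  par0 <- log(pmax(k0[off], 1e-3))
  if (free_fractions) par0 <- c(par0, rep(0, ns - 1))
  bt <- model$bin_times_ms
  stopifnot(length(histograms) == length(bt))

  unpack <- function(par) {
    k <- matrix(0, ns, ns)
    k[off] <- exp(par[seq_len(npar_r)])
    init <- NULL
    if (free_fractions) {
      w <- c(1, exp(par[npar_r + seq_len(ns - 1)]))
      init <- w / sum(w)
    }
    list(rates = k, init = init)
  }
  objective <- function(par) {
    u <- unpack(par)
    if (any(u$rates[off] > bounds[2]) || any(u$rates[off] < bounds[1]))
      return(1e12)
    tot <- 0
    for (i in seq_along(bt)) {
      fw <- pda_forward(model, bt[i], histograms[[i]]$n_library,
                        n_samples = n_samples, seed = seed + i,
                        rates = u$rates, init = u$init)
      tot <- tot + .pda_chi2(histograms[[i]]$counts, fw$prob, n_samples)
    }
    tot
  }
  # Pairwise coordinate descent before the full simplex: optimize each
  # forward/backward rate couple (k_ij, k_ji) in its own 2-D simplex,
  # cycling over the couples, then polish over all parameters at once.
  # The full 6-D simplex alone stalls in the long flat valley coupling
  # the dominant exchange rates; 2-D sub-simplexes converge reliably.
  pairs <- list()
  idxmat <- matrix(0L, ns, ns)
  idxmat[off] <- seq_along(off)
  for (i in seq_len(ns - 1)) for (j in seq.int(i + 1, ns))
    pairs <- c(pairs, list(c(idxmat[i, j], idxmat[j, i])))
  par <- par0
  for (cyc in 1:3) {
    for (pp in pairs) {
      f2 <- function(q) { p2 <- par; p2[pp] <- q; objective(p2) }
      o2 <- optim(par[pp], f2, method = "Nelder-Mead",
                  control = list(maxit = 120, reltol = 1e-6))
      par[pp] <- o2$par
    }
  }
  opt <- optim(par, objective, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-6))
  opt2 <- optim(opt$par, objective, method = "Nelder-Mead",
                control = list(maxit = maxit, reltol = 1e-6))
  if (opt2$value < opt$value) opt <- opt2
  # polish at a higher forward sample count: the seed-fixed Monte-Carlo
  # noise of the cheap objective is small but parameter-dependent, and the
  # simplex otherwise drifts along weakly identified directions to align
  # with it; quadrupling the samples shrinks that pull for the final steps
  ns_hi <- 4 * n_samples
  objective_hi <- function(par) {
    u <- unpack(par)
    if (any(u$rates[off] > bounds[2]) || any(u$rates[off] < bounds[1]))
      return(1e12)
    tot <- 0
    for (i in seq_along(bt)) {
      fw <- pda_forward(model, bt[i], histograms[[i]]$n_library,
                        n_samples = ns_hi, seed = seed + 31L * i,
                        rates = u$rates, init = u$init)
      tot <- tot + .pda_chi2(histograms[[i]]$counts, fw$prob, ns_hi)
    }
    tot
  }
  opt <- optim(opt$par, objective_hi, method = "Nelder-Mead",
               control = list(maxit = 150, reltol = 1e-6))
  u <- unpack(opt$par)
  per_bin <- vapply(seq_along(bt), function(i) {
    fw <- pda_forward(model, bt[i], histograms[[i]]$n_library,
                      n_samples = ns_hi, seed = seed + 31L * i,
                      rates = u$rates, init = u$init)
    .pda_chi2(histograms[[i]]$counts, fw$prob, ns_hi)
  }, numeric(1))
  dof <- sum(vapply(histograms, function(h) sum(h$counts > 0), numeric(1)))
  dof <- max(dof - length(par0), 1)
  frac <- if (free_fractions) u$init else {
    tmp <- kinetic_scheme(u$rates, sch$distances, sch$lifetimes,
                          sch$labels, sch$constants)
    tryCatch(stationary_distribution(tmp),
             error = function(e) rep(NA_real_, ns))
  }
  dimnames(u$rates) <- dimnames(sch$rates)
  at_bounds <- any(u$rates[off] > 0.98 * bounds[2])
  if (at_bounds)
    warning("fitted rates at the upper bound; result is unreliable")
  structure(
    list(rates = u$rates, fractions = 100 * frac / sum(frac),
         chi2_per_bin = setNames(per_bin, paste0(bt, "ms")),
         chi2_global = sum(per_bin) / dof,
         convergence = opt$convergence, at_bounds = at_bounds,
         free_fractions = free_fractions),
    class = "pda_fit"
  )
}

#' Prepare PDA histograms from a burst-selected stream
#'
#' Bins the bursts at each configured bin time and returns, per bin time,
#' the PR histogram and the photon-count library the forward model resamples
#' from.
#'
#' @param stream A `photon_stream`.
#' @param spans Burst spans (filtered).
#' @param model A [pda_model()].
#' @return Named list of `list(counts, n_library, n_windows)`.
#' @export
pda_prepare <- function(stream, spans, model) {
  out <- lapply(model$bin_times_ms, function(b) {
    bw <- bin_bursts(stream, spans, b, model$min_photons)
    h <- pr_histogram(bw, model$grid_E)
    list(counts = h$counts, n_library = bw$n, n_windows = h$n_windows)
  })
  names(out) <- paste0(model$bin_times_ms, "ms")
  out
}

#' Restart-averaged PDA fit
#'
#' Repeats the global fit from several uniform initial rate values and
#' reports means and standard deviations across restarts (the published
#' robustness protocol: initial rates 1, 0.5 and 0.75 ms^-1, bounds 0-10).
#' Restarts disagreeing by more than 50 % (relative) on any rate flag the
#' result as multi-modal.
#'
#' @inheritParams pda_fit_global
#' @param initial_values Initial rate values, one restart each.
#' @return Object of class `pda_robust`: `rates_mean`, `rates_sd` (ms^-1),
#'   `fractions_mean`, `fractions_sd` (percent), `chi2_global` per restart,
#'   `multi_modal`, `fits` (the individual `pda_fit`s).
#' @export
pda_robustness <- function(histograms, model,
                           initial_values = c(1, 0.5, 0.75),
                           bounds = c(0, 10), n_samples = 3e4, seed = 1,
                           free_fractions = FALSE, maxit = 400) {
  fits <- lapply(initial_values, function(v)
    pda_fit_global(histograms, model, initial_rates = v, bounds = bounds,
                   n_samples = n_samples, seed = seed,
                   free_fractions = free_fractions, maxit = maxit))
  ns <- nrow(fits[[1]]$rates)
  arr <- simplify2array(lapply(fits, function(f) f$rates))
  rates_mean <- apply(arr, c(1, 2), mean)
  rates_sd <- apply(arr, c(1, 2), sd)
  fr <- do.call(rbind, lapply(fits, function(f) f$fractions))
  off <- row(rates_mean) != col(rates_mean)
  rel_range <- (apply(arr, c(1, 2), max) - apply(arr, c(1, 2), min)) /
    pmax(rates_mean, 1e-12)
  multi_modal <- any(rel_range[off] > 0.5)
  structure(
    list(rates_mean = rates_mean, rates_sd = rates_sd,
         fractions_mean = colMeans(fr), fractions_sd = apply(fr, 2, sd),
         chi2_global = vapply(fits, function(f) f$chi2_global, numeric(1)),
         multi_modal = multi_modal, fits = fits),
    class = "pda_robust"
  )
}

#' @export
print.pda_robust <- function(x, ...) {
  cat("Restart-averaged dynamic PDA fit (", length(x$fits), "restarts )\n")
  ns <- nrow(x$rates_mean)
  lab <- names(x$fractions_mean)
  if (is.null(lab)) lab <- rownames(x$rates_mean)
  for (i in seq_len(ns)) for (j in seq_len(ns)) {
    if (i == j) next
    cat(sprintf("  k_%d,%d = %.2f +/- %.2f ms^-1\n", i, j,
                x$rates_mean[i, j], x$rates_sd[i, j]))
  }
  cat("  fractions (%):",
      paste(sprintf("%s %.1f +/- %.1f", lab, x$fractions_mean,
                    x$fractions_sd), collapse = ", "), "\n")
  cat(sprintf("  global chi2/dof: %s%s\n",
              paste(round(x$chi2_global, 2), collapse = ", "),
              if (x$multi_modal) "  [flagged multi-modal]" else ""))
  invisible(x)
}
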