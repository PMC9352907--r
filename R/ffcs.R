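# Species-filtered fluorescence correlation spectroscopy: TCSPC microtime
# filters that statistically separate two FRET sub-ensembles, weighted
# multi-tau correlation, and a global diffusion + exchange-relaxation fit.

# stack donor-excitation photons into (detector x coarse-microtime) pattern
# bins; returns the 1-based stacked bin index per photon (NA outside the
# donor window)
.pattern_bin <- function(stream, n_mt_bins) {
  half_ns <- attr(stream, "pie_period_ns") / 2
  mt <- microtime_ns(stream)
  dex <- mt < half_ns
  b <- floor(mt / (half_ns / n_mt_bins))
  b[b >= n_mt_bins] <- n_mt_bins - 1
  idx <- (stream$detector - 1L) * n_mt_bins + b + 1L
  idx[!dex] <- NA_integer_
  idx
}

#' Build species microtime filters
#'
#' Constructs TCSPC unmixing filters for two (or more) FRET sub-ensembles
#' selected by corrected-efficiency windows. Species microtime patterns are
#' taken from the donor-excitation photons of bursts inside each window
#' (stacked over the four detection channels); the background pattern comes
#' from inter-burst photons. The filters are the variance-minimizing
#' weighted-least-squares unmixing weights: with normalized patterns M and
#' the weighting built from the fitted mixture, `F = (M W M^T)^-1 M W`, so
#' that applying filter s to the calibration data recovers that species'
#' photon count in expectation and the weights across species + background
#' sum to 1 in every microtime bin.
#'
#' @param stream A `photon_stream`.
#' @param bursts Scored burst table (with corrected `E`).
#' @param spans The spans the table was built from.
#' @param species_windows Named list of efficiency windows, e.g.
#'   `list(O1 = c(0.17, 0.25), O2 = c(0.65, 0.75))`.
#' @param n_mt_bins Coarse microtime bins per detection channel.
#' @return Object of class `species_filter`: `weights` (rows = species +
#'   background, columns = stacked pattern bins), `patterns`, `species`,
#'   `n_mt_bins`, `condition_number`.
#' @export
build_filters <- function(stream, bursts, spans,
                          species_windows = list(O1 = c(0.17, 0.25),
                                                 O2 = c(0.65, 0.75)),
                          n_mt_bins = 64) {
  pbin <- .pattern_bin(stream, n_mt_bins)
  nb <- 4L * n_mt_bins
  in_burst <- rep(FALSE, nrow(stream))
  if (nrow(spans))
    in_burst[sequence(spans$i_end - spans$i_start + 1L,
                      from = spans$i_start)] <- TRUE

  pat <- list()
  for (s in names(species_windows)) {
    w <- species_windows[[s]]
    sel <- bursts$burst_id[!is.na(bursts$E) & bursts$E >= w[1] &
                             bursts$E <= w[2]]
    sp <- spans[match(sel, spans$burst_id), , drop = FALSE]
    idx <- if (nrow(sp))
      sequence(sp$i_end - sp$i_start + 1L, from = sp$i_start) else integer()
    bins <- pbin[idx]
    bins <- bins[!is.na(bins)]
    if (length(bins) < 1e4)
      warning("species ", s, " pattern built from only ", length(bins),
              " photons; filters will be noisy")
    if (length(bins) < 100)
      stop("species window ", s, " selects too few photons")
    pat[[s]] <- tabulate(bins, nbins = nb)
  }
  bg_bins <- pbin[!in_burst]
  bg_bins <- bg_bins[!is.na(bg_bins)]
  pat[["background"]] <- tabulate(bg_bins, nbins = nb)

  M <- do.call(rbind, lapply(pat, function(p) p / sum(p)))
  total <- pbin[!is.na(pbin)]
  S <- tabulate(total, nbins = nb)
  use <- S > 0 & colSums(M) > 0
  Mu <- M[, use, drop = FALSE]
  Su <- S[use]
  # amplitude fit, then the self-consistent weighting
  A0 <- crossprod(t(Mu) / pmax(Su, 1), Su / pmax(Su, 1))  # M W S with W=1/S
  XtX <- Mu %*% (t(Mu) / pmax(Su, 1))
  amp <- tryCatch(solve(XtX, A0), error = function(e)
    stop("species microtime patterns are near-collinear (condition number ",
         format(kappa(XtX, exact = TRUE), digits = 3),
         "); unmixing impossible"))
  Shat <- pmax(drop(t(Mu) %*% amp), 1e-12)
  MW <- t(t(Mu) / Shat)
  G <- Mu %*% t(MW)
  cn <- kappa(G, exact = TRUE)
  if (cn > 1e8)
    stop("species microtime patterns are near-collinear ",
         "(condition number ", format(cn, digits = 3),
         "); unmixing impossible")
  Fw <- solve(G, MW)
  weights <- matrix(0, nrow(M), nb, dimnames = list(names(pat), NULL))
  weights[, use] <- Fw
  structure(list(weights = weights, patterns = M,
                 species = names(species_windows), n_mt_bins = n_mt_bins,
                 condition_number = cn, used_bins = use),
            class = "species_filter")
}

#' Filtered photon counts
#'
#' Applies each species filter to a stream and returns the expected photon
#' count per species (+ background); on the calibration mixture these match
#' the true species counts in expectation.
#'
#' @param stream A `photon_stream`.
#' @param filters A `species_filter`.
#' @return Named numeric vector of filtered counts.
#' @export
filtered_counts <- function(stream, filters) {
  pbin <- .pattern_bin(stream, filters$n_mt_bins)
  pbin <- pbin[!is.na(pbin)]
  S <- tabulate(pbin, nbins = ncol(filters$weights))
  drop(filters$weights %*% S)
}

#' Species-filtered correlation functions
#'
#' Bins the filter-weighted donor-excitation photon stream onto a uniform
#' time grid and computes the two species autocorrelations and the two
#' cross-correlations with a multi-tau correlator. Uncertainties come from
#' a block decomposition of the acquisition into equal-duration segments.
#'
#' @param stream A `photon_stream`.
#' @param filters A `species_filter` (two species).
#' @param bin_us Correlator base bin in microseconds.
#' @param n_per_cascade Lags per multi-tau cascade.
#' @param n_cascades Number of cascades (lag range ~
#'   `bin_us * n_per_cascade * 2^n_cascades`).
#' @param n_blocks Blocks for the error estimate.
#' @return List of four data frames (`sACF_1`, `sACF_2`, `sCCF_12`,
#'   `sCCF_21`) with columns `lag_s`, `G`, `err`, `kind`.
#' @export
correlate_filtered <- function(stream, filters, bin_us = 2,
                               n_per_cascade = 16, n_cascades = 14,
                               n_blocks = 10) {
  stopifnot(length(filters$species) == 2L)
  pbin <- .pattern_bin(stream, filters$n_mt_bins)
  keep <- !is.na(pbin)
  t_s <- photon_times(stream)[keep]
  w1 <- filters$weights[1, pbin[keep]]
  w2 <- filters$weights[2, pbin[keep]]
  dur <- attr(stream, "duration_s")
  if (is.null(dur)) dur <- max(t_s)
  bin_s <- bin_us * 1e-6
  blk <- dur / n_blocks
  n_bins_blk <- floor(blk / bin_s)

  combos <- list(sACF_1 = c(1, 1), sACF_2 = c(2, 2),
                 sCCF_12 = c(1, 2), sCCF_21 = c(2, 1))
  acc <- NULL
  for (b in seq_len(n_blocks)) {
    t0 <- (b - 1) * blk
    inb <- t_s >= t0 & t_s < t0 + n_bins_blk * bin_s
    x1 <- cpp_bin_weights(t_s[inb], w1[inb], bin_s, t0, n_bins_blk)
    x2 <- cpp_bin_weights(t_s[inb], w2[inb], bin_s, t0, n_bins_blk)
    sig <- list(x1, x2)
    gb <- lapply(combos, function(cc)
      cpp_multitau(sig[[cc[1]]], sig[[cc[2]]], bin_s, n_per_cascade,
                   n_cascades))
    if (is.null(acc)) {
      acc <- lapply(gb, function(g)
        list(lag = g$lag_s, G = matrix(NA_real_, length(g$G), n_blocks)))
    }
    for (k in names(gb)) {
      m <- min(length(gb[[k]]$G), nrow(acc[[k]]$G))
      acc[[k]]$G[seq_len(m), b] <- gb[[k]]$G[seq_len(m)]
    }
  }
  out <- lapply(names(acc), function(k) {
    Gm <- rowMeans(acc[[k]]$G, na.rm = TRUE)
    err <- apply(acc[[k]]$G, 1, sd, na.rm = TRUE) / sqrt(n_blocks)
    data.frame(lag_s = acc[[k]]$lag, G = Gm, err = err, kind = k)
  })
  names(out) <- names(acc)
  out
}

# diffusion factor of the 3-D Gaussian confocal model
.g_diff <- function(tau_s, tau_diff_s, rho) {
  1 / ((1 + tau_s / tau_diff_s) * sqrt(1 + tau_s / (rho^2 * tau_diff_s)))
}

#' Global diffusion + relaxation fit of filtered correlation curves
#'
#' Fits the four species correlation curves jointly with
#' `G(tau) = G0 * Gdiff(tau; tau_D, rho) * (1 + A exp(-tau/tau_R))`,
#' sharing a single relaxation time `tau_R` across curves; the diffusion
#' time and the axial/lateral ratio are fixed (calibration quantities).
#' Cross-correlation kinetic amplitudes may be negative.
#'
#' @param curves List of four curves from [correlate_filtered()].
#' @param tau_diff_us Fixed diffusion time, microseconds.
#' @param rho Fixed axial/lateral ratio of the confocal volume.
#' @param lag_range_s Lags used in the fit. The default upper bound sits
#'   well below the diffusion time so the slowly varying diffusion factor
#'   cannot compensate shape mismatch with the relaxation term; the
#'   exchange relaxation of interest lives one to two decades below it.
#' @param tau_r_init_us Starting relaxation time.
#' @return Object of class `fcs_fit`: `tau_R_us` with standard error,
#'   `amplitudes` (per curve, with SE), `G0`, `chi2_reduced`, `fitted`
#'   (per-curve model values), flags.
#' @export
fit_fcs_global <- function(curves, tau_diff_us = 469, rho = 4.6,
                           lag_range_s = c(4e-6, 3e-4),
                           tau_r_init_us = 100) {
  stopifnot(length(curves) == 4L)
  dat <- do.call(rbind, curves)
  dat <- dat[dat$lag_s >= lag_range_s[1] & dat$lag_s <= lag_range_s[2] &
               is.finite(dat$G) & is.finite(dat$err) & dat$err > 0, ]
  dat$curve <- factor(dat$kind, levels = names(curves))
  td <- tau_diff_us * 1e-6

  # start values: amplitude from the smallest usable lag, sign of the
  # kinetic term from curve type
  g0 <- vapply(names(curves), function(k) {
    d <- dat[dat$kind == k, ]
    d$G[which.min(d$lag_s)]
  }, numeric(1))
  a0 <- ifelse(grepl("ACF", names(curves)), 0.3, -0.3)
  p0 <- c(log_tauR = log(tau_r_init_us * 1e-6), G0 = g0, A = a0)

  resid_fun <- function(p) {
    tauR <- exp(p[1])
    G0 <- p[2:5][as.integer(dat$curve)]
    A <- p[6:9][as.integer(dat$curve)]
    model <- G0 * .g_diff(dat$lag_s, td, rho) *
      (1 + A * exp(-dat$lag_s / tauR))
    (dat$G - model) / dat$err
  }
  fit <- minpack.lm::nls.lm(par = p0, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200))
  p <- unname(fit$par)
  tauR_us <- exp(p[1]) * 1e6
  se <- tryCatch(unname(sqrt(diag(vcov_nlslm(fit)))), error = function(e)
    rep(NA_real_, 9))
  A_hat <- p[6:9]
  A_se <- se[6:9]
  sig <- abs(A_hat) / A_se
  dof <- nrow(dat) - length(p)
  chi2 <- fit$deviance / dof
  unident <- all(!is.finite(sig)) || max(abs(A_hat), na.rm = TRUE) < 1e-3
  if (unident)
    warning("kinetic amplitudes are consistent with zero; ",
            "tau_R is unidentifiable (static mixture?)")
  fitted <- lapply(names(curves), function(k) {
    d <- dat[dat$kind == k, ]
    i <- match(k, levels(dat$curve))
    data.frame(lag_s = d$lag_s,
               G = p[1 + i] * .g_diff(d$lag_s, td, rho) *
                 (1 + p[5 + i] * exp(-d$lag_s / exp(p[1]))))
  })
  names(fitted) <- names(curves)
  structure(
    list(tau_R_us = tauR_us,
         tau_R_se_us = tauR_us * se[1],
         G0 = setNames(p[2:5], names(curves)),
         amplitudes = setNames(A_hat, names(curves)),
         amplitude_se = setNames(A_se, names(curves)),
         amplitude_significance = setNames(sig, names(curves)),
         tau_diff_us = tau_diff_us, rho = rho,
         chi2_reduced = chi2, n_points = nrow(dat),
         converged = fit$info %in% 1:4, unidentifiable = unident,
         fitted = fitted),
    class = "fcs_fit"
  )
}

# parameter covariance of an nls.lm fit (residuals already err-weighted)
vcov_nlslm <- function(fit) {
  dof <- length(fit$fvec) - length(fit$par)
  s2 <- fit$deviance / dof
  solve(fit$hessian) * s2
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat(sprintf("Global fFCS fit: tau_R = %.1f +/- %.1f us ", x$tau_R_us,
              x$tau_R_se_us))
  cat(sprintf("(tau_diff fixed %.0f us, rho %.1f), chi2/dof = %.2f\n",
              x$tau_diff_us, x$rho, x$chi2_reduced))
  for (k in names(x$amplitudes))
    cat(sprintf("  %s: G0 = %.4f, A = %+.3f +/- %.3f\n", k, x$G0[k],
                x$amplitudes[k], x$amplitude_se[k]))
  invisible(x)
}
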