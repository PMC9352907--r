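# Subpopulation TCSPC decay fitting and static / dynamic FRET lines for
# E-versus-lifetime diagnostics.

# Gaussian-IRF-convolved exponential decay density (exponentially modified
# Gaussian), evaluated stably on the log scale.
.exgauss <- function(t, tau, mu, sigma) {
  z <- (sigma^2 / tau - (t - mu)) / (sqrt(2) * sigma)
  logh <- -log(tau) + sigma^2 / (2 * tau^2) - (t - mu) / tau +
    pnorm(sqrt(2) * z, lower.tail = FALSE, log.p = TRUE)
  exp(logh)
}

#' Fit a multi-exponential fluorescence decay
#'
#' Maximum-likelihood fit under Poisson counting statistics of an
#' IRF-convolved sum of exponentials plus a flat background to a TCSPC
#' microtime histogram. The IRF is Gaussian with known mean and width.
#'
#' @param microtimes_ns Photon microtimes in ns (after the excitation
#'   pulse); typically pooled donor-channel photons.
#' @param n_components Number of exponential components (1-3).
#' @param irf_mean_ns,irf_sigma_ns Gaussian IRF parameters, ns.
#' @param window_ns Fit window (upper microtime bound), ns.
#' @param bin_ns Histogram channel width, ns.
#' @param seed Seed for the multi-start jitter of initial lifetimes.
#' @return Object of class `decay_model`: `lifetimes_ns` (decreasing),
#'   `amplitudes` (sum 1), `background_fraction`, `chi2_reduced`,
#'   `residuals` (weighted), `logLik`, `n_photons`, `converged`.
#' @export
fit_decay <- function(microtimes_ns, n_components = 2,
                      irf_mean_ns = 1.5, irf_sigma_ns = 0.106,
                      window_ns = 25, bin_ns = 0.05, seed = NULL) {
  stopifnot(n_components >= 1, n_components <= 3)
  mt <- microtimes_ns[microtimes_ns >= 0 & microtimes_ns < window_ns]
  if (length(mt) < 500)
    warning("fewer than 500 photons; decay-fit parameters will be noisy")
  breaks <- seq(0, window_ns, by = bin_ns)
  nb <- length(breaks) - 1L
  # direct channel indexing (epsilon guards photons quantized exactly onto
  # bin edges against floating-point aliasing)
  counts <- tabulate(pmin(floor((mt + 1e-9) / bin_ns), nb - 1L) + 1L,
                     nbins = nb)
  mids <- breaks[-1] - bin_ns / 2
  N <- sum(counts)

  model_p <- function(par) {
    k <- n_components
    tau <- exp(par[1:k])
    w <- c(1, exp(par[seq_len(k - 1) + k]))  # first amplitude pinned to 1
    w <- w / sum(w)
    bgf <- 1 / (1 + exp(-par[2 * k]))        # background fraction, logit
    dens <- rep(0, nb)
    for (i in seq_len(k))
      dens <- dens + w[i] * .exgauss(mids, tau[i], irf_mean_ns, irf_sigma_ns)
    p <- (1 - bgf) * dens * bin_ns / sum(dens * bin_ns) + bgf / nb
    pmax(p, 1e-300)
  }
  nll <- function(par) {
    p <- model_p(par)
    -sum(counts * log(p))
  }
  # moment-based initial lifetime, components spread geometrically
  tau0 <- max(mean(mt) - irf_mean_ns, 0.1)
  spread <- switch(n_components, 1, c(2, 0.5), c(3, 1, 0.3))
  init <- c(log(tau0 * spread), rep(0, n_components - 1), -4)
  fit <- .with_seed(seed, optim(init, nll, method = "Nelder-Mead",
                                control = list(maxit = 5000,
                                               reltol = 1e-10)))
  if (fit$convergence != 0) {
    fit2 <- optim(fit$par, nll, method = "Nelder-Mead",
                  control = list(maxit = 5000, reltol = 1e-10))
    if (fit2$value <= fit$value) fit <- fit2
  }
  par <- fit$par
  k <- n_components
  tau <- exp(par[1:k])
  w <- c(1, exp(par[seq_len(k - 1) + k]))
  w <- w / sum(w)
  ord <- order(tau, decreasing = TRUE)
  p <- model_p(par)
  lambda <- N * p
  resid <- (counts - lambda) / sqrt(pmax(lambda, 1))
  dof <- nb - (2 * k)  # lifetimes + relative amplitudes + background
  structure(
    list(lifetimes_ns = tau[ord], amplitudes = w[ord],
         background_fraction = 1 / (1 + exp(-par[2 * k])),
         chi2_reduced = sum(resid^2) / dof,
         residuals = resid, mids_ns = mids, counts = counts,
         fitted = lambda, logLik = -fit$value, n_photons = N,
         converged = fit$convergence == 0),
    class = "decay_model"
  )
}

#' @export
print.decay_model <- function(x, ...) {
  cat(sprintf("%d-exponential decay fit over %d photons\n",
              length(x$lifetimes_ns), x$n_photons))
  for (i in seq_along(x$lifetimes_ns))
    cat(sprintf("  tau%d = %.3f ns (amplitude %.3f)\n", i,
                x$lifetimes_ns[i], x$amplitudes[i]))
  cat(sprintf("  background fraction %.4f, reduced chi2 = %.3f\n",
              x$background_fraction, x$chi2_reduced))
  invisible(x)
}

#' Compare decay models with increasing component counts
#'
#' Fits 1..`max_components` exponentials and reports the reduced
#' chi-squared sequence, the standard model-selection diagnostic for
#' subpopulation decays.
#'
#' @inheritParams fit_decay
#' @param max_components Largest model to fit.
#' @return List of `decay_model` objects, one per component count, with a
#'   `chi2` attribute vector.
#' @export
compare_decay_models <- function(microtimes_ns, max_components = 3, ...) {
  fits <- lapply(seq_len(max_components), function(k)
    fit_decay(microtimes_ns, n_components = k, ...))
  attr(fits, "chi2") <- vapply(fits, function(f) f$chi2_reduced, numeric(1))
  fits
}

#' Pool donor microtimes from a FRET subpopulation
#'
#' Selects bursts whose corrected efficiency lies in `e_range` and pools the
#' donor-excitation donor-channel microtimes of their photons for
#' subpopulation-specific lifetime analysis.
#'
#' @param stream A `photon_stream`.
#' @param bursts Burst table from [score_bursts()] (rows must carry
#'   `burst_id` matching the `spans` used to build them).
#' @param spans The burst spans ([apbs_search()] output) the table was built
#'   from.
#' @param e_range Efficiency interval, e.g. `c(0.4, 0.6)`.
#' @return Numeric vector of microtimes (ns) with attributes `e_range` and
#'   `n_bursts` (selection provenance).
#' @export
subpopulation_select <- function(stream, bursts, spans, e_range) {
  stopifnot(length(e_range) == 2L)
  if (e_range[1] >= e_range[2]) stop("empty efficiency range")
  sel <- bursts$burst_id[!is.na(bursts$E) & bursts$E >= e_range[1] &
                           bursts$E <= e_range[2]]
  if (!length(sel)) stop("no bursts in the requested efficiency range")
  sp <- spans[match(sel, spans$burst_id), ]
  idx <- sequence(sp$i_end - sp$i_start + 1L, from = sp$i_start)
  keep <- excitation_slot(stream)[idx] == 1L &
    stream$detector[idx] %in% c(1L, 2L)
  out <- microtime_ns(stream)[idx][keep]
  attr(out, "e_range") <- e_range
  attr(out, "n_bursts") <- length(sel)
  out
}

#' Donor-only reference lifetime from high-stoichiometry bursts
#'
#' Pools donor-channel microtimes of the donor-only population
#' (stoichiometry window, default 0.75-1) and fits a single exponential —
#' the standard in-situ determination of the donor-only lifetime tau_D.
#'
#' @param stream A `photon_stream`.
#' @param bursts Scored burst table ([score_bursts()] output, unfiltered).
#' @param spans The burst spans the table was built from.
#' @param s_range Stoichiometry window selecting donor-only molecules.
#' @param ... Passed to [fit_decay()].
#' @return A one-component `decay_model`; `lifetimes_ns[1]` is tau_D.
#' @export
donor_only_lifetime <- function(stream, bursts, spans,
                                s_range = c(0.75, 1), ...) {
  sel <- bursts$burst_id[!is.na(bursts$S) & bursts$S > s_range[1] &
                           bursts$S <= s_range[2]]
  if (!length(sel)) stop("no donor-only bursts in the stoichiometry window")
  sp <- spans[match(sel, spans$burst_id), ]
  idx <- sequence(sp$i_end - sp$i_start + 1L, from = sp$i_start)
  keep <- excitation_slot(stream)[idx] == 1L &
    stream$detector[idx] %in% c(1L, 2L)
  fit_decay(microtime_ns(stream)[idx][keep], n_components = 1, ...)
}

# numerically integrated E and fluorescence-weighted lifetime for a mean
# distance with Gaussian linker broadening
.linker_locus <- function(Rbar, constants, linker) {
  if (linker <= 0) {
    E <- efficiency_from_distance(Rbar, constants)
    return(cbind(E = E, tau = constants$tauD * (1 - E)))
  }
  t(vapply(Rbar, function(r) {
    g <- seq(max(r - 5 * linker, 1), r + 5 * linker, length.out = 201)
    w <- dnorm(g, r, linker)
    w <- w / sum(w)
    E <- efficiency_from_distance(g, constants)
    tau <- constants$tauD * (1 - E)
    tf <- sum(w * tau^2) / sum(w * tau)    # fluorescence-weighted lifetime
    c(E = sum(w * E), tau = tf)            # count-weighted mean efficiency
  }, c(E = 0, tau = 0)))
}

#' Static FRET line
#'
#' The locus of non-exchanging species in the E-versus-donor-lifetime plane.
#' With zero linker width this is exactly `E = 1 - tau/tauD`; with a finite
#' apparent linker the dye-linker distance distribution shifts the
#' fluorescence-weighted lifetime, and the moment-corrected curve is
#' represented as a cubic polynomial of E against tau (maximum deviation
#' from the numerically integrated curve below 0.005).
#'
#' @param constants A [fret_constants()].
#' @param linker Apparent linker length in Angstrom (default from
#'   `constants`).
#' @return Object of class `fret_line` with `kind = "static"`, polynomial
#'   `coef`, and the generating `grid` (tau, E).
#' @export
static_fret_line <- function(constants = fret_constants(),
                             linker = constants$linker_length) {
  stopifnot(linker >= 0)
  Rbar <- exp(seq(log(8), log(400), length.out = 400))
  loc <- .linker_locus(Rbar, constants, linker)
  tau <- loc[, "tau"]
  E <- loc[, "E"]
  keep <- tau > 1e-4 & tau < constants$tauD - 1e-6
  cf <- stats::lm(E[keep] ~ poly(tau[keep], 3, raw = TRUE))$coefficients
  structure(list(kind = "static", coef = unname(cf), tauD = constants$tauD,
                 linker = linker, grid = data.frame(tau = tau, E = E)),
            class = "fret_line")
}

#' Dynamic FRET line between two exchanging states
#'
#' Parametric curve of the burst-averaged (E, fluorescence-weighted tau) as
#' the fraction of time spent in state A sweeps 0 to 1 (species-weighted
#' fluorescence-averaged lifetime algebra). Bursts mixing two states during
#' a transit fall on this curve, to the right of the static line.
#'
#' @param tau_a_ns,tau_b_ns Donor lifetimes of the two endpoint states, ns.
#' @param constants A [fret_constants()].
#' @param n_points Curve resolution.
#' @return Object of class `fret_line` with `kind = "dynamic"` and the curve
#'   in `grid` (columns `x` = fraction in A, `tau`, `E`).
#' @export
dynamic_fret_line <- function(tau_a_ns, tau_b_ns,
                              constants = fret_constants(),
                              n_points = 201) {
  if (abs(tau_a_ns - tau_b_ns) < 1e-9)
    stop("endpoint lifetimes are equal; dynamic line is degenerate")
  x <- seq(0, 1, length.out = n_points)
  tau_sp <- x * tau_a_ns + (1 - x) * tau_b_ns       # species-averaged
  tau_f <- (x * tau_a_ns^2 + (1 - x) * tau_b_ns^2) / tau_sp
  E <- 1 - tau_sp / constants$tauD
  structure(list(kind = "dynamic", tauD = constants$tauD,
                 endpoints_ns = c(tau_a_ns, tau_b_ns),
                 grid = data.frame(x = x, tau = tau_f, E = E)),
            class = "fret_line")
}

#' Evaluate a FRET line at given lifetimes
#'
#' @param line A `fret_line`.
#' @param tau_ns Lifetimes (ns) at which to evaluate E.
#' @return Efficiencies.
#' @export
fret_line_E <- function(line, tau_ns) {
  if (line$kind == "static") {
    if (line$linker <= 0) return(1 - tau_ns / line$tauD)
    drop(cbind(1, tau_ns, tau_ns^2, tau_ns^3) %*% line$coef)
  } else {
    # dynamic: interpolate the parametric curve in tau
    stats::approx(line$grid$tau, line$grid$E, xout = tau_ns, rule = 2)$y
  }
}
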