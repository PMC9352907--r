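# Synthetic-data generator: time-tagged PIE photon streams from freely
# diffusing molecules undergoing Markov switching between conformational
# states.
#
# The transit model is deliberately simple: a molecule contributes a
# constant-intensity burst over an exponentially distributed dwell in the
# confocal volume. Photon statistics within the transit (state-dependent
# donor/acceptor splitting, lifetimes, crosstalk, direct excitation,
# detection factor, background) carry all the information the downstream
# burst, PDA and fFCS analyses rely on; the 3-D beam geometry only shapes
# the diffusion term of the correlation functions and is parameterized
# separately in the FCS fit.

# restore the caller's RNG state after a seeded simulation
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Acquisition configuration for the photon-stream simulator
#'
#' @param pie_period_ns Pulsed-interleaved-excitation cycle in ns (50 ns =
#'   20 MHz; donor pulse at 0, acceptor pulse at half period).
#' @param microtime_resolution_ns TCSPC channel width in ns; must divide the
#'   PIE period.
#' @param irf_mean_ns,irf_fwhm_ns Gaussian instrument-response mean and FWHM
#'   in ns.
#' @param duration_s Acquisition duration in seconds.
#' @param background_rates Named counts/s per detection channel
#'   (`D_par`, `D_perp`, `A_par`, `A_perp`).
#' @return Object of class `acquisition_config`.
#' @export
acquisition_config <- function(pie_period_ns = 50,
                               microtime_resolution_ns = 0.05,
                               irf_mean_ns = 1.5, irf_fwhm_ns = 0.25,
                               duration_s = 10,
                               background_rates = c(D_par = 500, D_perp = 500,
                                                    A_par = 350,
                                                    A_perp = 350)) {
  stopifnot(pie_period_ns > 0, microtime_resolution_ns > 0, duration_s > 0)
  n_ch <- pie_period_ns / microtime_resolution_ns
  if (abs(n_ch - round(n_ch)) > 1e-9)
    stop("microtime resolution must divide the PIE period")
  stopifnot(all(background_rates >= 0), length(background_rates) == 4L)
  structure(
    list(pie_period_ns = pie_period_ns,
         microtime_resolution_ns = microtime_resolution_ns,
         n_channels = as.integer(round(n_ch)),
         irf_mean_ns = irf_mean_ns,
         irf_sigma_ns = irf_fwhm_ns / (2 * sqrt(2 * log(2))),
         duration_s = duration_s,
         background_rates = background_rates),
    class = "acquisition_config"
  )
}

#' Correction factors of the detection system
#'
#' @param DE Direct excitation of the acceptor at the donor wavelength.
#' @param Lk Donor leakage into the acceptor channel.
#' @param g Detection-correction (gamma) factor applied to the donor channel.
#' @return Object of class `correction_set`.
#' @export
correction_set <- function(DE = 0.05, Lk = 0.08, g = 0.85) {
  stopifnot(DE >= 0, Lk >= 0, g > 0)
  structure(list(DE = DE, Lk = Lk, g = g), class = "correction_set")
}

#' Molecule model for the simulator
#'
#' @param scheme A [kinetic_scheme()] describing the conformational states.
#' @param sigma Fractional width of the per-state distance distribution
#'   (SD = `sigma * R`), drawn once per burst and state.
#' @param brightness Mean detected donor-excitation counts/ms at E = 0.
#' @param transit_mean_ms Mean confocal transit (exponential), ms.
#' @param corrections Ground-truth [correction_set()] distorting the emitted
#'   counts; analysis recovers E when using the same values.
#' @param contaminant_fractions Probabilities that a burst molecule is
#'   donor-only / acceptor-only rather than doubly labeled.
#' @param acceptor_lifetime_ns Acceptor fluorescence lifetime, ns.
#' @param acceptor_dark_fraction Probability that a doubly labeled
#'   molecule's acceptor sits in a dark, non-FRET state for the whole
#'   transit (it then emits like a donor-only molecule but is labelled
#'   species 4 in the ground truth). Off by default.
#' @return Object of class `molecule_model`.
#' @export
molecule_model <- function(scheme, sigma = 0.045, brightness = 200,
                           transit_mean_ms = 0.5,
                           corrections = correction_set(),
                           contaminant_fractions = c(donor_only = 0.1,
                                                     acceptor_only = 0.05),
                           acceptor_lifetime_ns = 3.5,
                           acceptor_dark_fraction = 0) {
  stopifnot(inherits(scheme, "kinetic_scheme"), sigma >= 0, brightness > 0,
            transit_mean_ms > 0, acceptor_dark_fraction >= 0,
            acceptor_dark_fraction < 1)
  cf <- contaminant_fractions
  stopifnot(all(cf >= 0), all(cf <= 1), sum(cf) < 1)
  structure(
    list(scheme = scheme, sigma = sigma, brightness = brightness,
         transit_mean_ms = transit_mean_ms, corrections = corrections,
         contaminant_fractions = cf,
         acceptor_lifetime_ns = acceptor_lifetime_ns,
         acceptor_dark_fraction = acceptor_dark_fraction),
    class = "molecule_model"
  )
}

#' Simulate a state trajectory of a kinetic scheme
#'
#' Gillespie realization of the continuous-time Markov chain: exponential
#' holding times with rate `sum_j k_ij`, next state drawn proportionally to
#' `k_ij`.
#'
#' @param scheme A [kinetic_scheme()].
#' @param duration_ms Trajectory length in ms.
#' @param seed Integer seed (`NULL` to use the current RNG stream).
#' @param init Initial-state distribution; default the stationary
#'   distribution (falls back to uniform for non-irreducible schemes).
#' @return Data frame with columns `state`, `t0_ms`, `t1_ms`.
#' @export
simulate_state_path <- function(scheme, duration_ms, seed = NULL,
                                init = NULL) {
  if (is.null(init)) {
    init <- tryCatch(stationary_distribution(scheme),
                     error = function(e)
                       rep(1 / length(scheme$labels),
                           length(scheme$labels)))
  }
  .with_seed(seed, {
    seg <- cpp_ctmc_segments(duration_ms, scheme$rates, as.numeric(init))
    data.frame(state = seg$state, t0_ms = seg$t0_ms, t1_ms = seg$t1_ms)
  })
}

# internal: state segments for many bursts at once
.ctmc_segments <- function(scheme, durations_ms, init) {
  cpp_ctmc_segments(durations_ms, scheme$rates, as.numeric(init))
}

# Per-segment photon generation shared by simulate_burst/simulate_experiment.
# seg: data.frame(path, state, t0_ms, t1_ms); E_seg: proximity-relevant FRET
# efficiency per segment (NA for contaminant segments handled by caller).
# Returns a data.frame of photons with times in ms relative to the segment
# frame (absolute offset added by caller).
.segment_photons <- function(seg, E_seg, tau_seg_ns, model, acq,
                             species_seg) {
  co <- model$corrections
  c0 <- model$brightness                      # counts/ms at E = 0
  dur <- seg$t1_ms - seg$t0_ms
  ca <- co$g * c0                             # acceptor-excitation brightness

  # detected rates per excitation x detection class, counts/ms
  # (species: 1 doubly labeled, 2 donor-only, 3 acceptor-only,
  #  4 doubly labeled with dark acceptor = donor-only photophysics)
  no_acceptor <- species_seg %in% c(2L, 4L)
  r_dd <- ifelse(species_seg == 3, 0, c0 * (1 - E_seg))
  r_da <- ifelse(species_seg == 3, c0 * co$DE * co$g,
                 c0 * (co$g * E_seg + co$Lk * (1 - E_seg) +
                         ifelse(no_acceptor, 0, co$DE * co$g)))
  r_aa <- ifelse(no_acceptor, 0, ca)

  one_class <- function(rate, class_id) {
    n <- rpois(length(rate), rate * dur)
    idx <- rep.int(seq_along(n), n)
    if (!length(idx))
      return(data.frame(seg_idx = integer(), t_ms = numeric(),
                        class = integer()))
    data.frame(seg_idx = idx,
               t_ms = seg$t0_ms[idx] + runif(length(idx)) * dur[idx],
               class = class_id)
  }
  ph <- rbind(one_class(r_dd, 1L), one_class(r_da, 2L), one_class(r_aa, 3L))
  if (!nrow(ph)) return(ph)

  # microtimes: nanoseconds after the start of the PIE cycle
  half <- acq$pie_period_ns / 2
  tau <- ifelse(ph$class == 1L, tau_seg_ns[ph$seg_idx],
                model$acceptor_lifetime_ns)
  mt <- rexp(nrow(ph), 1 / tau) +
    rnorm(nrow(ph), acq$irf_mean_ns, acq$irf_sigma_ns)
  mt <- mt %% half                      # keep within the excitation window
  mt <- mt + ifelse(ph$class == 3L, half, 0)
  ph$microtime_ns <- mt
  # 50:50 polarizing split, no depolarization physics
  pol <- runif(nrow(ph)) < 0.5
  ph$detector <- ifelse(ph$class == 1L, ifelse(pol, 1L, 2L),
                        ifelse(pol, 3L, 4L))
  ph
}

# assemble a photon_stream object from raw columns
.make_stream <- function(t_s, microtime_ns, detector, molecule, state,
                         species, acq, model = NULL) {
  o <- order(t_s)
  res <- acq$microtime_resolution_ns
  df <- data.frame(
    macrotime = floor(t_s[o] * 1e9 / acq$pie_period_ns),
    # epsilon guards channel values that round-trip through ns against
    # floating-point collapse onto the previous channel
    microtime = as.integer(floor(microtime_ns[o] / res + 1e-6)),
    detector = as.integer(detector[o]),
    molecule = molecule[o],
    state = state[o],
    species = species[o]
  )
  structure(df, class = c("photon_stream", "data.frame"),
            pie_period_ns = acq$pie_period_ns,
            microtime_resolution_ns = res,
            irf_mean_ns = acq$irf_mean_ns,
            irf_sigma_ns = acq$irf_sigma_ns,
            duration_s = acq$duration_s)
}

#' Photon arrival times in seconds
#' @param stream A `photon_stream`.
#' @return Numeric vector of arrival times (s).
#' @export
photon_times <- function(stream) {
  stream$macrotime * attr(stream, "pie_period_ns") * 1e-9
}

#' Excitation slot of each photon
#'
#' Derived from the microtime: photons in the first half of the PIE cycle
#' follow the donor pulse, photons in the second half the acceptor pulse.
#'
#' @param stream A `photon_stream`.
#' @return Integer vector: 1 = donor excitation, 2 = acceptor excitation.
#' @export
excitation_slot <- function(stream) {
  res <- attr(stream, "microtime_resolution_ns")
  half_ch <- attr(stream, "pie_period_ns") / 2 / res
  ifelse(stream$microtime < half_ch, 1L, 2L)
}

#' Microtime in nanoseconds
#' @param stream A `photon_stream`.
#' @return Numeric vector (ns after the donor pulse).
#' @export
microtime_ns <- function(stream) {
  stream$microtime * attr(stream, "microtime_resolution_ns")
}

#' Simulate a single-molecule transit
#'
#' One burst: an exponential transit during which photons are emitted with
#' state-dependent donor/acceptor splitting, distorted by the ground-truth
#' corrections, with TCSPC microtimes drawn from the state lifetime convolved
#' with the Gaussian IRF.
#'
#' @param model A [molecule_model()].
#' @param acq An [acquisition_config()].
#' @param seed Integer seed.
#' @param species 1 = doubly labeled, 2 = donor-only, 3 = acceptor-only,
#'   4 = doubly labeled with a dark acceptor.
#' @return A `photon_stream` fragment (times starting at 0) with ground-truth
#'   columns `molecule`, `state`, `species`.
#' @export
simulate_burst <- function(model, acq, seed = NULL, species = 1L) {
  .with_seed(seed, {
    dur <- rexp(1, 1 / model$transit_mean_ms)
    .simulate_bursts_raw(model, acq, start_s = 0, durations_ms = dur,
                         species = species)
  })
}

# vectorized burst engine; returns a photon_stream
.simulate_bursts_raw <- function(model, acq, start_s, durations_ms, species) {
  sch <- model$scheme
  n_b <- length(durations_ms)
  pi0 <- tryCatch(stationary_distribution(sch),
                  error = function(e) rep(1 / length(sch$labels),
                                          length(sch$labels)))
  dbl <- which(species == 1L)
  seg_list <- list()
  if (length(dbl)) {
    seg <- .ctmc_segments(sch, durations_ms[dbl], pi0)
    seg$path <- dbl[seg$path]
    seg_list$dbl <- seg
  }
  oth <- which(species != 1L)
  if (length(oth)) {
    seg_list$oth <- data.frame(path = oth, state = 0L, t0_ms = 0,
                               t1_ms = durations_ms[oth])
  }
  seg <- do.call(rbind, seg_list)
  seg_species <- species[seg$path]

  # per-burst, per-state distance broadening (one draw per burst per state)
  ns <- length(sch$labels)
  Rd <- matrix(rnorm(n_b * ns, mean = rep(sch$distances, each = n_b),
                     sd = model$sigma * rep(sch$distances, each = n_b)),
               n_b, ns)
  Rd[Rd < 1] <- 1
  Eb <- 1 / (1 + (Rd / sch$constants$R0)^6)

  E_seg <- numeric(nrow(seg))
  tau_seg <- rep(sch$constants$tauD, nrow(seg))
  isd <- seg_species == 1L
  E_seg[isd] <- Eb[cbind(seg$path[isd], seg$state[isd])]
  tau_seg[isd] <- sch$lifetimes[seg$state[isd]]
  E_seg[seg_species != 1L] <- 0        # no acceptor (or dark): no transfer

  ph <- .segment_photons(seg, E_seg, tau_seg, model, acq, seg_species)
  if (!nrow(ph)) {
    return(.make_stream(numeric(), numeric(), integer(), integer(),
                        integer(), integer(), acq))
  }
  burst_of <- seg$path[ph$seg_idx]
  t_abs <- start_s[burst_of] + ph$t_ms * 1e-3
  st <- ifelse(seg_species[ph$seg_idx] == 1L, seg$state[ph$seg_idx], 0L)
  .make_stream(t_abs, ph$microtime_ns, ph$detector, burst_of, st,
               species[burst_of], acq)
}

#' Simulate a full acquisition
#'
#' Places single-molecule transits on a sparse arrival process over the
#' configured duration, adds uncorrelated background photons in every
#' detection channel, and returns the time-ordered photon stream with
#' ground-truth labels (`molecule` 0 = background, `state` 0 = not a
#' doubly-labeled FRET photon).
#'
#' @param model A [molecule_model()].
#' @param acq An [acquisition_config()]; `duration_s` sets the acquisition
#'   length.
#' @param n_bursts Number of molecule transits to place.
#' @param seed Integer seed; the same seed reproduces the stream exactly.
#' @return A `photon_stream`.
#' @export
simulate_experiment <- function(model, acq, n_bursts, seed = NULL) {
  .with_seed(seed, {
    dur_s <- acq$duration_s
    if (n_bursts > 0) {
      starts <- sort(runif(n_bursts, 0, dur_s))
      durs <- rexp(n_bursts, 1 / model$transit_mean_ms)
      cf <- model$contaminant_fractions
      u <- runif(n_bursts)
      species <- ifelse(u < cf[1], 2L, ifelse(u < cf[1] + cf[2], 3L, 1L))
      if (model$acceptor_dark_fraction > 0) {
        dark <- runif(n_bursts) < model$acceptor_dark_fraction
        species[species == 1L & dark] <- 4L
      }
      overlap <- mean(starts[-1] < starts[-n_bursts] +
                        durs[-n_bursts] * 1e-3)
      if (is.finite(overlap) && overlap > 0.05)
        warning(sprintf(paste0("%.1f%% of transits overlap; the ",
                               "single-molecule regime is violated"),
                        100 * overlap))
      mol <- .simulate_bursts_raw(model, acq, starts, durs, species)
    } else {
      mol <- NULL
    }
    # background photons, uniform in time and microtime
    bg <- acq$background_rates
    nbg <- rpois(4, bg * dur_s)
    bg_t <- runif(sum(nbg), 0, dur_s)
    bg_det <- rep.int(1:4, nbg)
    bg_mt <- runif(sum(nbg), 0, acq$pie_period_ns)
    if (is.null(mol)) {
      out <- .make_stream(bg_t, bg_mt, bg_det, rep(0L, sum(nbg)),
                          rep(0L, sum(nbg)), rep(0L, sum(nbg)), acq)
    } else {
      t_all <- c(photon_times(mol), bg_t)
      mt_all <- c(microtime_ns(mol), bg_mt)
      det <- c(mol$detector, bg_det)
      molid <- c(mol$molecule, rep(0L, sum(nbg)))
      stt <- c(mol$state, rep(0L, sum(nbg)))
      spc <- c(mol$species, rep(0L, sum(nbg)))
      out <- .make_stream(t_all, mt_all, det, molid, stt, spc, acq)
    }
    attr(out, "n_bursts") <- n_bursts
    out
  })
}
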