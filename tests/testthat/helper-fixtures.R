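# Shared fixtures: small seeded simulations reused across test files.
# Everything is generated in code; sizes are kept small enough for a
# routine test run while leaving the statistics informative.

ox_scheme <- function() pdi_scheme("oxidized")
rd_scheme <- function() pdi_scheme("reduced")

# a one-state scheme at a given distance (static control)
one_state_scheme <- function(R = 62.3, tau = NULL, constants = fret_constants()) {
  E <- efficiency_from_distance(R, constants)
  if (is.null(tau)) tau <- constants$tauD * (1 - E)
  kinetic_scheme(matrix(0, 2, 2), distances = c(R, R),
                 lifetimes = c(tau, tau), labels = c("A", "B"),
                 constants = constants)
}

# cached medium-size reduced-WT experiment shared by burst/lifetime tests
.cache <- new.env()

rd_experiment <- function() {
  if (is.null(.cache$rd)) {
    sch <- rd_scheme()
    mod <- molecule_model(sch)
    acq <- acquisition_config(duration_s = 40)
    st <- simulate_experiment(mod, acq, n_bursts = 2000, seed = 101)
    spans <- apbs_search(st)
    tab <- score_bursts(st, spans)
    sel <- select_fret_bursts(tab)
    .cache$rd <- list(stream = st, spans = spans, bursts = tab,
                      selected = sel, model = mod, acq = acq)
  }
  .cache$rd
}

# shared two-state O1<->O2 exchange stream at the reduced WT rates,
# used by the fFCS unit tests and the acceptance suite
ffcs_experiment <- function() {
  if (is.null(.cache$ffcs)) {
    k <- matrix(c(0, 8.49, 6.28, 0), 2, 2, byrow = TRUE)
    sch <- kinetic_scheme(k, c(80, 55), c(2.75, 0.91),
                          labels = c("O1", "O2"))
    mod <- molecule_model(sch, contaminant_fractions = c(0.05, 0.03))
    acq <- acquisition_config(duration_s = 60)
    st <- simulate_experiment(mod, acq, n_bursts = 6000, seed = 301)
    spans <- apbs_search(st)
    sel <- select_fret_bursts(score_bursts(st, spans))
    .cache$ffcs <- list(stream = st, spans = spans, sel = sel,
                        scheme = sch)
  }
  .cache$ffcs
}

# Gillespie occupancy oracle: long trajectory time-average (independent of
# the linear-algebra stationary solve)
gillespie_occupancy <- function(scheme, total_ms = 2e4, seed = 1) {
  path <- simulate_state_path(scheme, total_ms, seed = seed)
  dwell <- tapply(path$t1_ms - path$t0_ms, path$state, sum)
  out <- rep(0, length(scheme$labels))
  out[as.integer(names(dwell))] <- dwell
  out / sum(out)
}
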