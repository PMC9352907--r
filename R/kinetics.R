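# Three-state kinetic scheme of conformational exchange and the closed-form
# conversions between rates, occupancies, FRET observables and free-energy
# barriers.
#
# State indexing convention used throughout the package:
#   1 = O1 (open,  ~80 A interdye distance, donor lifetime 2.75 ns)
#   2 = O2 (open,  ~55 A,                   donor lifetime 0.91 ns)
#   3 = C  (closed,~42 A,                   donor lifetime 0.25 ns)
# Off-diagonal rates k[i, j] mean the transition i -> j in ms^-1.

#' Photophysical constants of a FRET pair
#'
#' Container for the Forster radius and donor-only lifetime used by all
#' distance/efficiency/lifetime conversions. Defaults describe the
#' Atto550/Atto647N pair used for the PDI 88/467 construct.
#'
#' @param R0 Forster radius in Angstrom.
#' @param tauD Donor-only fluorescence lifetime in ns.
#' @param kappa2 Orientation factor (metadata only, not used in computation).
#' @param refractive_index Refractive index (metadata only).
#' @param linker_length Apparent dye-linker length in Angstrom, used when
#'   drawing static FRET lines.
#' @return An object of class `fret_constants`.
#' @export
#' @examples
#' fc <- fret_constants()
#' efficiency_from_distance(62.3, fc)  # 0.5 at the Forster radius
fret_constants <- function(R0 = 62.3, tauD = 3.2, kappa2 = 2 / 3,
                           refractive_index = 1.4, linker_length = 5) {
  stopifnot(is.numeric(R0), length(R0) == 1L, R0 > 0)
  stopifnot(is.numeric(tauD), length(tauD) == 1L, tauD > 0)
  stopifnot(linker_length >= 0)
  structure(
    list(R0 = R0, tauD = tauD, kappa2 = kappa2,
         refractive_index = refractive_index,
         linker_length = linker_length),
    class = "fret_constants"
  )
}

#' Multi-state kinetic scheme
#'
#' Bundles the state-resolved structural parameters (mean interdye distance,
#' donor lifetime in presence of the acceptor) with the off-diagonal rate
#' matrix of a continuous-time Markov chain.
#'
#' @param rates Square numeric matrix of transition rates in ms^-1;
#'   `rates[i, j]` is the rate of the i -> j transition. The diagonal is
#'   ignored (set internally to minus the row sum).
#' @param distances Mean interdye distance per state, Angstrom.
#' @param lifetimes Donor lifetime per state in presence of the acceptor, ns.
#' @param labels State labels; defaults to `O1`, `O2`, `C` for three states.
#' @param constants A [fret_constants()] object; lifetimes must not exceed
#'   its `tauD`.
#' @return An object of class `kinetic_scheme` with elements `rates`
#'   (off-diagonal matrix, zero diagonal), `distances`, `lifetimes`,
#'   `labels`, `constants`.
#' @export
kinetic_scheme <- function(rates, distances, lifetimes,
                           labels = NULL, constants = fret_constants()) {
  rates <- as.matrix(rates)
  n <- nrow(rates)
  if (n < 2L || ncol(rates) != n)
    stop("'rates' must be a square matrix with at least 2 states")
  if (any(rates[row(rates) != col(rates)] < 0))
    stop("all transition rates must be >= 0")
  diag(rates) <- 0
  if (length(distances) != n || any(distances <= 0))
    stop("'distances' must be ", n, " positive values (Angstrom)")
  if (length(lifetimes) != n || any(lifetimes <= 0) ||
      any(lifetimes > constants$tauD))
    stop("'lifetimes' must be in (0, tauD] ns")
  if (is.null(labels))
    labels <- if (n == 3L) c("O1", "O2", "C") else paste0("S", seq_len(n))
  dimnames(rates) <- list(labels, labels)
  structure(
    list(rates = rates, distances = setNames(distances, labels),
         lifetimes = setNames(lifetimes, labels), labels = labels,
         constants = constants),
    class = "kinetic_scheme"
  )
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("Kinetic scheme with", length(x$labels), "states:",
      paste(x$labels, collapse = ", "), "\n")
  cat("Distances (A):", paste(x$distances, collapse = ", "), "\n")
  cat("Lifetimes (ns):", paste(x$lifetimes, collapse = ", "), "\n")
  cat("Rates (ms^-1):\n")
  print(x$rates)
  invisible(x)
}

#' CTMC generator of a kinetic scheme
#'
#' Returns the generator matrix Q (ms^-1) with `Q[i, j] = k_ij` off the
#' diagonal and diagonals set to minus the row sums.
#'
#' @param scheme A [kinetic_scheme()].
#' @return Square numeric matrix, rows summing to zero.
#' @export
generator_matrix <- function(scheme) {
  Q <- scheme$rates
  diag(Q) <- -rowSums(Q)
  Q
}

# strong connectivity of the directed graph with edges where k > 0
.reachable <- function(adj, from) {
  n <- nrow(adj)
  seen <- rep(FALSE, n)
  seen[from] <- TRUE
  repeat {
    new <- seen | (seen %*% adj > 0)
    if (all(new == seen)) break
    seen <- as.vector(new)
  }
  seen
}

#' Stationary distribution of a kinetic scheme
#'
#' Solves pi Q = 0 with sum(pi) = 1 by a null-space computation on the
#' transposed generator (exact for the small schemes used here), after
#' checking that the chain is irreducible.
#'
#' @param scheme A [kinetic_scheme()].
#' @return Named numeric vector of equilibrium occupancies summing to 1.
#' @export
#' @examples
#' sch <- pdi_scheme("oxidized")
#' round(100 * stationary_distribution(sch), 1)  # 22.6 / 43.6 / 33.8 %
stationary_distribution <- function(scheme) {
  Q <- generator_matrix(scheme)
  n <- nrow(Q)
  adj <- (scheme$rates > 0) * 1
  for (i in seq_len(n)) {
    fwd <- .reachable(adj, i)
    if (!all(fwd)) {
      # a state the chain can enter but never leave makes the long-run
      # occupancy degenerate; report which
      absorbing <- which(rowSums(scheme$rates) == 0)
      lab <- if (length(absorbing))
        paste(scheme$labels[absorbing], collapse = ", ") else
        paste(scheme$labels[!fwd], collapse = ", ")
      stop("kinetic scheme is not irreducible (absorbing/unreachable: ",
           lab, ")")
    }
  }
  dec <- svd(t(Q))
  pi_raw <- dec$v[, n]
  if (dec$d[n] > 1e-8 * max(dec$d))
    stop("generator has no null space; invalid scheme")
  pi_raw <- pi_raw / sum(pi_raw)
  if (any(pi_raw < -1e-10))
    stop("stationary solve produced negative occupancy; invalid scheme")
  setNames(pmax(pi_raw, 0) / sum(pmax(pi_raw, 0)), scheme$labels)
}

#' Two-state exchange relaxation time
#'
#' The relaxation time of a two-state exchange, `tau_R = 1/(k_ab + k_ba)`,
#' converted from ms to microseconds.
#'
#' @param k_ab,k_ba Forward and backward rate in ms^-1.
#' @return Relaxation time in microseconds.
#' @export
#' @examples
#' two_state_relaxation_time(4.50, 2.38)  # ~145 us
two_state_relaxation_time <- function(k_ab, k_ba) {
  stopifnot(k_ab >= 0, k_ba >= 0)
  if (k_ab + k_ba <= 0) stop("both rates are zero; no relaxation")
  1000 / (k_ab + k_ba)
}

#' Eigen-relaxation spectrum of a kinetic scheme
#'
#' Negated reciprocals of the nonzero eigenvalues of the generator, in
#' microseconds. For a two-state scheme this is the single time
#' `1/(k_ab + k_ba)`.
#'
#' @param scheme A [kinetic_scheme()].
#' @return Numeric vector of relaxation times (us), increasing order. If the
#'   generator has additional (numerically) zero eigenvalues, e.g. a frozen
#'   chain, the corresponding infinite times are returned with a warning.
#' @export
relaxation_spectrum <- function(scheme) {
  Q <- generator_matrix(scheme)
  ev <- eigen(Q, only.values = TRUE)$values
  ev <- Re(ev[order(abs(Re(ev)))])
  scale <- max(abs(ev), 1e-12)
  nonzero <- ev[-1]  # drop the stationary eigenvalue
  if (any(abs(nonzero) < 1e-10 * scale) || scale <= 1e-12) {
    warning("generator has (near-)zero relaxation eigenvalues; ",
            "infinite relaxation times flagged")
  }
  tau <- ifelse(abs(nonzero) < 1e-10 * max(scale, 1), Inf,
                -1000 / nonzero)
  sort(tau)
}

#' Kramers free-energy barriers from rate constants
#'
#' Converts every nonzero transition rate into an activation free energy
#' using the Kramers relation `k = A exp(-dG / kBT)`, i.e.
#' `dG_ij = ln(A / k_ij)` in units of kBT, with the rate expressed in s^-1.
#'
#' @param scheme A [kinetic_scheme()].
#' @param prefactor Kramers pre-exponential factor A in s^-1.
#' @return Object of class `free_energy_landscape`: list with `barriers`
#'   (matrix, kBT units; `Inf` for zero rates, `NA` on the diagonal) and
#'   `prefactor`.
#' @export
#' @examples
#' kramers_barriers(pdi_scheme("reduced"))$barriers["O2", "C"]  # ~6.8 kBT
kramers_barriers <- function(scheme, prefactor = 1e5) {
  stopifnot(prefactor > 0)
  k_s <- scheme$rates * 1000  # ms^-1 -> s^-1
  barriers <- matrix(NA_real_, nrow(k_s), ncol(k_s),
                     dimnames = dimnames(k_s))
  off <- row(k_s) != col(k_s)
  barriers[off] <- ifelse(k_s[off] > 0, log(prefactor / k_s[off]), Inf)
  if (any(is.infinite(barriers[off])))
    message("zero rates present: corresponding barriers are infinite")
  structure(list(barriers = barriers, prefactor = prefactor),
            class = "free_energy_landscape")
}

#' Cycle-flux diagnostic for a three-state scheme
#'
#' For a triangular scheme, detailed balance requires the product of rates
#' around the cycle to equal the product in the reverse direction. Fitted
#' rates need not satisfy this; the log-ratio quantifies the deviation.
#'
#' @param scheme A three-state [kinetic_scheme()].
#' @return List with `forward` and `backward` cycle products (ms^-3) and
#'   `log_ratio` (0 under detailed balance).
#' @export
cycle_flux <- function(scheme) {
  k <- scheme$rates
  stopifnot(nrow(k) == 3L)
  fwd <- k[1, 2] * k[2, 3] * k[3, 1]
  bwd <- k[2, 1] * k[3, 2] * k[1, 3]
  list(forward = fwd, backward = bwd,
       log_ratio = if (fwd > 0 && bwd > 0) log(fwd / bwd) else NA_real_)
}

# --- FRET observable conversions --------------------------------------------

#' FRET efficiency from interdye distance
#'
#' `E = 1 / (1 + (R/R0)^6)`.
#'
#' @param R Distance(s) in Angstrom; must be > 0.
#' @param constants A [fret_constants()].
#' @return Efficiency in (0, 1).
#' @export
efficiency_from_distance <- function(R, constants = fret_constants()) {
  if (any(!is.finite(R)) || any(R <= 0)) stop("distance must be positive")
  1 / (1 + (R / constants$R0)^6)
}

#' Interdye distance from FRET efficiency
#'
#' Inverse Forster relation `R = R0 ((1-E)/E)^(1/6)`.
#'
#' @param E Efficiency in (0, 1).
#' @param constants A [fret_constants()].
#' @return Distance in Angstrom.
#' @export
distance_from_efficiency <- function(E, constants = fret_constants()) {
  if (any(E <= 0) || any(E >= 1)) stop("efficiency must be in (0, 1)")
  constants$R0 * ((1 - E) / E)^(1 / 6)
}

#' FRET efficiency from donor lifetime
#'
#' `E = 1 - tau / tauD` for the donor lifetime in presence of the acceptor.
#' A lifetime above the donor-only lifetime signals a mis-assigned
#' donor-only species and is rejected.
#'
#' @param tau Donor lifetime(s) in ns, in (0, tauD].
#' @param tauD Donor-only lifetime in ns.
#' @return Efficiency in `[0, 1)`.
#' @export
efficiency_from_lifetime <- function(tau, tauD = 3.2) {
  if (any(tau <= 0)) stop("lifetime must be positive")
  if (any(tau > tauD + 1e-12))
    stop("lifetime exceeds the donor-only lifetime (", tauD,
         " ns); check donor-only assignment")
  1 - tau / tauD
}

#' Interdye distance from donor lifetime
#'
#' Composition of [efficiency_from_lifetime()] with the inverse Forster
#' relation; round-trips with [efficiency_from_distance()] to machine
#' precision.
#'
#' @param tau Donor lifetime(s) in ns, strictly below `constants$tauD`.
#' @param constants A [fret_constants()].
#' @return Distance in Angstrom.
#' @export
distance_from_lifetime <- function(tau, constants = fret_constants()) {
  if (any(tau >= constants$tauD))
    stop("lifetime at or above the donor-only lifetime implies infinite ",
         "distance")
  distance_from_efficiency(efficiency_from_lifetime(tau, constants$tauD),
                           constants)
}

# --- presets and rate tables -------------------------------------------------

#' State distance presets for the PDI 88/467 construct
#'
#' Two published parameterizations of the O1/O2/C interdye distances: the
#' fixed values used in the global PDA fits (80/55/42 A) and the values that
#' follow directly from the subpopulation lifetimes (2.75/0.91/0.25 ns)
#' through the Forster relation (84.2/53.4/41.3 A).
#'
#' @param set `"fixed"` or `"lifetime_derived"`.
#' @param constants A [fret_constants()].
#' @return Named numeric vector of distances (A) for O1, O2, C.
#' @export
pdi_distances <- function(set = c("fixed", "lifetime_derived"),
                          constants = fret_constants()) {
  set <- match.arg(set)
  if (set == "fixed")
    return(c(O1 = 80, O2 = 55, C = 42))
  setNames(distance_from_lifetime(c(2.75, 0.91, 0.25), constants),
           c("O1", "O2", "C"))
}

#' Published PDA rate table for PDI 88/467 and variants
#'
#' Loads the bundled table of globally fitted three-state exchange rates,
#' equilibrium state fractions and global chi-squared for oxidized and
#' reduced PDI 88/467 (WT and five active-site / interface variants).
#'
#' @return A data frame with columns `redox`, `variant`, `quantity`
#'   (`k_1,2` ... `k_3,2`, `pct_O1`, `pct_O2`, `pct_C`, `chi2_global`),
#'   `value` and `sd`.
#' @export
pdi_rate_table <- function() {
  path <- system.file("extdata", "table1_rates.csv", package = "fretdyn")
  read.csv(path, stringsAsFactors = FALSE)
}

#' Published kinetic scheme presets for PDI 88/467
#'
#' Builds a [kinetic_scheme()] from the bundled rate table.
#'
#' @param redox `"oxidized"` or `"reduced"`.
#' @param variant One of `"WT"`, `"AA/AA"`, `"CC/AA"`, `"AA/CC"`, `"R300H"`,
#'   `"W396A"`.
#' @param distances Distances per state (A); default the fixed PDA set.
#' @param constants A [fret_constants()].
#' @return A three-state [kinetic_scheme()].
#' @export
pdi_scheme <- function(redox = c("oxidized", "reduced"), variant = "WT",
                       distances = pdi_distances("fixed"),
                       constants = fret_constants()) {
  redox <- match.arg(redox)
  tab <- pdi_rate_table()
  tab <- tab[tab$redox == redox & tab$variant == variant, ]
  if (nrow(tab) == 0L) stop("unknown redox/variant combination")
  k <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    key <- sprintf("k_%d,%d", i, j)
    k[i, j] <- tab$value[tab$quantity == key]
  }
  kinetic_scheme(k, distances = distances,
                 lifetimes = c(2.75, 0.91, 0.25), constants = constants)
}

#' Published equilibrium state fractions
#'
#' The state-fraction rows of the bundled rate table. These are independent
#' fit outputs of the published global PDA, not recomputed from the rates
#' (for some variants the two disagree).
#'
#' @inheritParams pdi_scheme
#' @return Named numeric vector (percent) for O1, O2, C.
#' @export
pdi_fractions <- function(redox = c("oxidized", "reduced"), variant = "WT") {
  redox <- match.arg(redox)
  tab <- pdi_rate_table()
  tab <- tab[tab$redox == redox & tab$variant == variant, ]
  setNames(
    c(tab$value[tab$quantity == "pct_O1"],
      tab$value[tab$quantity == "pct_O2"],
      tab$value[tab$quantity == "pct_C"]),
    c("O1", "O2", "C")
  )
}

#' Read / write a rate-constant table
#'
#' Single-scheme CSV interchange format with header
#' `state_from,state_to,rate_ms^-1` and a companion state table
#' `state,label,distance_A,lifetime_ns`. The O2 distance label "57" appearing
#' in some published tables is accepted as an alias for the default 55 A.
#'
#' @param rates_path Path to the rate CSV.
#' @param states_path Path to the companion state CSV; if `NULL`, the default
#'   O1/O2/C parameterization is used.
#' @param constants A [fret_constants()].
#' @return A [kinetic_scheme()].
#' @export
read_rate_table <- function(rates_path, states_path = NULL,
                            constants = fret_constants()) {
  rt <- read.csv(rates_path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("state_from", "state_to", "rate_ms^-1")
  if (!all(need %in% names(rt)))
    stop("rate table must have header ", paste(need, collapse = ","))
  if (is.null(states_path)) {
    labels <- c("O1", "O2", "C")
    distances <- pdi_distances("fixed")
    lifetimes <- c(2.75, 0.91, 0.25)
  } else {
    st <- read.csv(states_path, stringsAsFactors = FALSE)
    st <- st[order(st$state), ]
    labels <- st$label
    distances <- st$distance_A
    lifetimes <- st$lifetime_ns
  }
  n <- length(labels)
  k <- matrix(0, n, n)
  fi <- match(rt$state_from, seq_len(n))
  ti <- match(rt$state_to, seq_len(n))
  if (any(is.na(fi)) || any(is.na(ti)))
    stop("state indices outside 1..", n)
  k[cbind(fi, ti)] <- rt[["rate_ms^-1"]]
  kinetic_scheme(k, distances, lifetimes, labels, constants)
}

#' @rdname read_rate_table
#' @param scheme A [kinetic_scheme()] to serialize.
#' @export
write_rate_table <- function(scheme, rates_path, states_path = NULL) {
  n <- length(scheme$labels)
  idx <- which(row(scheme$rates) != col(scheme$rates), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  rt <- data.frame(state_from = idx[, 1], state_to = idx[, 2],
                   rate = scheme$rates[idx], check.names = FALSE)
  names(rt)[3] <- "rate_ms^-1"
  write.csv(rt, rates_path, row.names = FALSE, quote = FALSE)
  if (!is.null(states_path)) {
    st <- data.frame(state = seq_len(n), label = scheme$labels,
                     distance_A = as.numeric(scheme$distances),
                     lifetime_ns = as.numeric(scheme$lifetimes))
    write.csv(st, states_path, row.names = FALSE, quote = FALSE)
  }
  invisible(rates_path)
}
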