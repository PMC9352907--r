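# Burst search, corrected FRET efficiency / stoichiometry, and the
# burst-quality filter cascade (stoichiometry window, ALEX-2CDE, |TDX-TAA|).

#' All-photon burst search
#'
#' Sliding-window (Nir-type) search over all detection channels: a photon
#' belongs to a burst region when at least `min_in_window` photons fall in
#' the surrounding window; maximal runs of qualifying photons form candidate
#' bursts, and only bursts with strictly more than `min_counts` photons are
#' kept.
#'
#' @param stream A `photon_stream`.
#' @param window_ms Sliding-window length in ms.
#' @param min_counts Total-count threshold; bursts must exceed it strictly.
#' @param min_in_window Local-rate criterion: photons required inside the
#'   window centred on each photon.
#' @return Data frame of non-overlapping, time-ordered spans with columns
#'   `burst_id`, `i_start`, `i_end` (1-based photon indices), `t_start_s`,
#'   `duration_ms`, `counts`.
#' @export
apbs_search <- function(stream, window_ms = 0.5, min_counts = 40,
                        min_in_window = 20) {
  empty <- data.frame(burst_id = integer(), i_start = integer(),
                      i_end = integer(), t_start_s = numeric(),
                      duration_ms = numeric(), counts = integer())
  n <- nrow(stream)
  if (n == 0L) return(empty)
  t <- photon_times(stream)
  half <- window_ms * 1e-3 / 2
  in_win <- findInterval(t + half, t) - findInterval(t - half, t)
  ok <- in_win >= min_in_window
  if (!any(ok)) return(empty)
  # runs of qualifying photons, additionally split where the gap to the
  # previous photon exceeds the search window (separates bursts that have
  # no intervening background photon)
  gap_break <- c(FALSE, diff(t) > window_ms * 1e-3)
  start_flag <- ok & (!c(FALSE, ok[-n]) | gap_break)
  end_flag <- ok & (!c(ok[-1], FALSE) | c(gap_break[-1], FALSE))
  i0 <- which(start_flag)
  i1 <- which(end_flag)
  keep <- (i1 - i0 + 1L) > min_counts
  if (!any(keep)) return(empty)
  i0 <- i0[keep]
  i1 <- i1[keep]
  data.frame(burst_id = seq_along(i0), i_start = i0, i_end = i1,
             t_start_s = t[i0], duration_ms = (t[i1] - t[i0]) * 1e3,
             counts = i1 - i0 + 1L)
}

#' Corrected FRET efficiency and stoichiometry
#'
#' Standard alternating-excitation accounting: the FRET-induced acceptor
#' signal is `F_A = N_DA - Lk N_DD - DE N_AA`, then
#' `E = F_A / (F_A + g N_DD)` and `S = (F_A + g N_DD) /
#' (F_A + g N_DD + N_AA)`.
#'
#' @param n_dd,n_da,n_aa Channel counts (donor-excitation donor / acceptor
#'   detection, acceptor-excitation acceptor detection).
#' @param corrections A [correction_set()].
#' @return Data frame with columns `E`, `S`, `valid` (FALSE where a
#'   denominator vanished; such bursts are flagged, not dropped).
#' @export
compute_es <- function(n_dd, n_da, n_aa, corrections = correction_set()) {
  stopifnot(all(n_dd >= 0), all(n_da >= 0), all(n_aa >= 0))
  co <- corrections
  fa <- n_da - co$Lk * n_dd - co$DE * n_aa
  den_e <- fa + co$g * n_dd
  den_s <- den_e + n_aa
  valid <- is.finite(den_e) & abs(den_e) > 1e-12 & abs(den_s) > 1e-12
  E <- ifelse(valid, fa / den_e, NA_real_)
  S <- ifelse(valid, den_e / den_s, NA_real_)
  data.frame(E = E, S = S, valid = valid)
}

#' ALEX-2CDE photobleaching filter score
#'
#' Kernel-density asymmetry score between donor-excitation and
#' acceptor-excitation photon arrival patterns within each burst, computed
#' with an exponential kernel. Near 0 for well-interleaved streams,
#' approaching 100 when one excitation channel is confined to part of the
#' burst (e.g. mid-burst acceptor bleaching); infinite when either
#' excitation slot holds fewer than two photons.
#'
#' @param stream A `photon_stream`.
#' @param spans Burst spans from [apbs_search()].
#' @param kde_tau_us Kernel time constant in microseconds.
#' @return Numeric score per burst.
#' @export
alex_2cde <- function(stream, spans, kde_tau_us = 100) {
  if (!nrow(spans)) return(numeric())
  cpp_alex2cde(photon_times(stream), excitation_slot(stream),
               spans$i_start, spans$i_end, kde_tau_us * 1e-6)
}

#' |TDX - TAA| burst-asymmetry score
#'
#' Absolute difference between the duration-normalized mean arrival times of
#' donor-excitation and acceptor-excitation photons within a burst
#' (dimensionless, 0 for co-centred channels). Bursts with an empty
#' excitation channel get `Inf` and are removed by the filter threshold.
#'
#' @inheritParams alex_2cde
#' @return Numeric score per burst.
#' @export
tdx_taa_filter <- function(stream, spans) {
  if (!nrow(spans)) return(numeric())
  t <- photon_times(stream)
  slot <- excitation_slot(stream)
  vapply(seq_len(nrow(spans)), function(b) {
    i <- spans$i_start[b]:spans$i_end[b]
    dur <- spans$duration_ms[b] * 1e-3
    td <- t[i][slot[i] == 1L]
    ta <- t[i][slot[i] == 2L]
    if (!length(td) || !length(ta) || dur <= 0) return(Inf)
    abs(mean(td) - mean(ta)) / dur
  }, numeric(1))
}

#' Score bursts: counts, E/S, filters, mean lifetime
#'
#' Builds the full burst table from a stream and burst spans: per-channel
#' counts, corrected E and S, the ALEX-2CDE and |TDX-TAA| filter scores, and
#' the per-burst donor lifetime estimate (intensity-weighted mean microtime
#' of donor-excitation donor-channel photons minus the IRF mean).
#'
#' @param stream A `photon_stream`.
#' @param spans Burst spans from [apbs_search()].
#' @param corrections A [correction_set()].
#' @param kde_tau_us ALEX-2CDE kernel constant, microseconds.
#' @return Data frame with one row per burst: `burst_id`, `t_start_s`,
#'   `duration_ms`, `n_dd`, `n_da`, `n_aa`, `E`, `S`, `valid`, `alex2cde`,
#'   `tdx_taa`, `mean_tau_ns`.
#' @export
score_bursts <- function(stream, spans, corrections = correction_set(),
                         kde_tau_us = 100) {
  if (!nrow(spans)) {
    return(cbind(spans[, c("burst_id", "t_start_s", "duration_ms")],
                 data.frame(n_dd = integer(), n_da = integer(),
                            n_aa = integer(), E = numeric(), S = numeric(),
                            valid = logical(), alex2cde = numeric(),
                            tdx_taa = numeric(), mean_tau_ns = numeric())))
  }
  slot <- excitation_slot(stream)
  det <- stream$detector
  mt <- microtime_ns(stream)
  irf_mean <- attr(stream, "irf_mean_ns")
  idx <- rep.int(seq_len(nrow(spans)), spans$i_end - spans$i_start + 1L)
  ph <- sequence(spans$i_end - spans$i_start + 1L, from = spans$i_start)
  is_dd <- slot[ph] == 1L & det[ph] %in% c(1L, 2L)
  is_da <- slot[ph] == 1L & det[ph] %in% c(3L, 4L)
  is_aa <- slot[ph] == 2L & det[ph] %in% c(3L, 4L)
  cnt <- function(flag) {
    v <- integer(nrow(spans))
    tb <- tabulate(idx[flag], nbins = nrow(spans))
    v + tb
  }
  n_dd <- cnt(is_dd); n_da <- cnt(is_da); n_aa <- cnt(is_aa)
  es <- compute_es(n_dd, n_da, n_aa, corrections)
  # mean DD microtime per burst -> lifetime first-moment estimator
  sum_mt <- rep(0, nrow(spans))
  tb <- tapply(mt[ph][is_dd], idx[is_dd], sum)
  sum_mt[as.integer(names(tb))] <- tb
  mean_tau <- ifelse(n_dd > 0, sum_mt / n_dd - irf_mean, NA_real_)
  cbind(spans[, c("burst_id", "t_start_s", "duration_ms")],
        data.frame(n_dd = n_dd, n_da = n_da, n_aa = n_aa,
                   E = es$E, S = es$S, valid = es$valid,
                   alex2cde = alex_2cde(stream, spans, kde_tau_us),
                   tdx_taa = tdx_taa_filter(stream, spans),
                   mean_tau_ns = mean_tau))
}

#' Apply the burst-quality filter cascade
#'
#' Conjunction of the stoichiometry window, the ALEX-2CDE threshold and the
#' |TDX-TAA| threshold; order-invariant. Removal counts per criterion are
#' attached as attribute `removed`.
#'
#' @param bursts Burst table from [score_bursts()].
#' @param s_range Stoichiometry window keeping doubly labeled molecules.
#' @param alex_max ALEX-2CDE upper threshold.
#' @param tdxtaa_max |TDX-TAA| upper threshold.
#' @return Filtered burst table.
#' @export
select_fret_bursts <- function(bursts, s_range = c(0.25, 0.75),
                               alex_max = 14, tdxtaa_max = 0.5) {
  stopifnot(length(s_range) == 2L, s_range[1] < s_range[2])
  ok_s <- !is.na(bursts$S) & bursts$S >= s_range[1] & bursts$S <= s_range[2]
  ok_a <- is.finite(bursts$alex2cde) & bursts$alex2cde < alex_max
  ok_t <- is.finite(bursts$tdx_taa) & bursts$tdx_taa < tdxtaa_max
  ok_v <- bursts$valid
  out <- bursts[ok_s & ok_a & ok_t & ok_v, , drop = FALSE]
  attr(out, "removed") <- c(stoichiometry = sum(!ok_s),
                            alex2cde = sum(!ok_a),
                            tdx_taa = sum(!ok_t),
                            invalid = sum(!ok_v))
  out
}

#' FRET efficiency histogram over bursts
#'
#' @param bursts Burst table (filtered).
#' @param n_bins Number of bins.
#' @param range Efficiency range of the histogram.
#' @return List with `breaks`, `counts`, `mids`, `mean`, `sd`, `n`.
#' @export
fret_histogram <- function(bursts, n_bins = 50, range = c(-0.1, 1.1)) {
  E <- bursts$E[!is.na(bursts$E)]
  if (!length(E))
    stop("no bursts left to histogram; relax the filters or simulate more")
  breaks <- seq(range[1], range[2], length.out = n_bins + 1L)
  Ec <- pmin(pmax(E, range[1]), range[2])
  counts <- tabulate(findInterval(Ec, breaks, rightmost.closed = TRUE),
                     nbins = n_bins)
  list(breaks = breaks, counts = counts,
       mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
       mean = mean(E), sd = sd(E), n = length(E))
}

#' Write a burst table as CSV
#'
#' Fixed column order `burst_id, t_start_s, duration_ms, n_dd, n_da, n_aa,
#' E, S, alex2cde, tdx_taa, mean_tau_ns`.
#'
#' @param bursts Burst table.
#' @param path Output path.
#' @export
write_burst_table <- function(bursts, path) {
  cols <- c("burst_id", "t_start_s", "duration_ms", "n_dd", "n_da", "n_aa",
            "E", "S", "alex2cde", "tdx_taa", "mean_tau_ns")
  write.csv(bursts[, cols], path, row.names = FALSE)
  invisible(path)
}
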