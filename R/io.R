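# Configuration, the plain-text photon container, the pipeline driver and
# the rate-table reporter.

#' Default analysis configuration
#'
#' All constants of the analysis as named keys with their defaults:
#' corrections, burst search and filter thresholds, photophysical constants,
#' state parameterization, PDA and fFCS settings, and the Kramers prefactor.
#'
#' @return Nested named list (flat namespaces per stage).
#' @export
default_config <- function() {
  list(
    corrections = list(DE = 0.05, Lk = 0.08, g = 0.85),
    burst = list(window_ms = 0.5, min_counts = 40, min_in_window = 20,
                 s_range = c(0.25, 0.75), alex2cde_max = 14,
                 tdx_taa_max = 0.5, alex2cde_tau_us = 100),
    fret = list(R0_A = 62.3, tauD_ns = 3.2, sigma = 0.045,
                linker_A = 5,
                distances_A = c(O1 = 80, O2 = 55, C = 42),
                lifetimes_ns = c(O1 = 2.75, O2 = 0.91, C = 0.25)),
    pda = list(bin_times_ms = c(0.25, 0.5, 0.75, 1), grid_E = 100,
               min_photons = 10, rate_bounds_ms = c(0, 10),
               restart_values_ms = c(1, 0.5, 0.75)),
    ffcs = list(tau_diff_us = 469, rho = 4.6,
                species_windows = list(O1 = c(0.17, 0.25),
                                       O2 = c(0.65, 0.75))),
    kinetics = list(kramers_prefactor_s = 1e5),
    seed = 1L
  )
}

# recursively reject keys absent from the reference config
.check_keys <- function(cfg, ref, path = "") {
  bad <- setdiff(names(cfg), names(ref))
  if (length(bad))
    stop("unknown config key(s): ",
         paste0(path, bad, collapse = ", "))
  for (k in names(cfg)) {
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]])) &&
        is.list(cfg[[k]]))
      .check_keys(cfg[[k]], ref[[k]], paste0(path, k, "$"))
  }
  invisible(TRUE)
}

# merge user values over defaults (shallow per namespace)
.merge_cfg <- function(user, ref) {
  for (k in names(user)) {
    if (is.list(ref[[k]]) && is.list(user[[k]]) &&
        !is.null(names(ref[[k]])))
      ref[[k]] <- .merge_cfg(user[[k]], ref[[k]])
    else ref[[k]] <- user[[k]]
  }
  ref
}

#' Load an analysis configuration from YAML
#'
#' Unknown keys are rejected; missing keys fall back to [default_config()].
#' Basic sanity checks (ordered windows, positive constants) are applied.
#'
#' @param path Path to a YAML file, or `NULL` for the defaults.
#' @return Validated config list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    .check_keys(user, cfg)
    cfg <- .merge_cfg(user, cfg)
  }
  if (cfg$burst$s_range[1] >= cfg$burst$s_range[2])
    stop("config error: burst$s_range must be increasing")
  if (cfg$fret$R0_A <= 0 || cfg$fret$tauD_ns <= 0)
    stop("config error: photophysical constants must be positive")
  cfg
}

#' Write a configuration as YAML
#' @param cfg Config list.
#' @param path Output path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# short deterministic hash of a config (provenance tag)
.config_hash <- function(cfg) {
  s <- yaml::as.yaml(cfg)
  v <- utf8ToInt(s)
  h <- 5381
  for (x in v) h <- (h * 33 + x) %% 2^31
  sprintf("%08x", h)
}

#' Write a photon stream to the plain-text container
#'
#' The container is a single text file: a commented YAML header carrying the
#' acquisition metadata (PIE period, microtime resolution, IRF, duration,
#' schema version), followed by a CSV table of the per-photon records
#' (`macrotime` in clock ticks of one PIE period, `microtime` in TCSPC
#' channels, `detector` 1-4, and the ground-truth columns `molecule`,
#' `state`, `species` when present).
#'
#' @param stream A `photon_stream`.
#' @param path Output path.
#' @export
write_photon_stream <- function(stream, path) {
  meta <- list(schema = "fretdyn-photon-stream/1",
               pie_period_ns = attr(stream, "pie_period_ns"),
               microtime_resolution_ns =
                 attr(stream, "microtime_resolution_ns"),
               irf_mean_ns = attr(stream, "irf_mean_ns"),
               irf_sigma_ns = attr(stream, "irf_sigma_ns"),
               duration_s = attr(stream, "duration_s"),
               n_photons = nrow(stream))
  hdr <- paste0("# ", strsplit(yaml::as.yaml(meta), "\n")[[1]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(as.data.frame(stream), con, row.names = FALSE)
  invisible(path)
}

#' Read a photon stream from the plain-text container
#'
#' Validates the schema version, monotone macrotimes and the microtime
#' range; refuses truncated files rather than returning a partial stream.
#'
#' @param path Container path.
#' @return A `photon_stream`.
#' @export
read_photon_stream <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  if (!length(hdr)) stop("not a photon container: missing header")
  meta <- yaml::yaml.load(paste(sub("^# ", "", hdr), collapse = "\n"))
  if (!identical(meta$schema, "fretdyn-photon-stream/1"))
    stop("unsupported container schema: ", meta$schema)
  body <- lines[!startsWith(lines, "# ")]
  df <- read.csv(text = paste(body, collapse = "\n"))
  if (nrow(df) != meta$n_photons)
    stop("truncated container: expected ", meta$n_photons, " photons, got ",
         nrow(df))
  if (is.unsorted(df$macrotime))
    stop("invalid container: macrotimes are not nondecreasing")
  n_ch <- meta$pie_period_ns / meta$microtime_resolution_ns
  if (any(df$microtime < 0) || any(df$microtime >= n_ch))
    stop("invalid container: microtime outside the PIE period")
  structure(df, class = c("photon_stream", "data.frame"),
            pie_period_ns = meta$pie_period_ns,
            microtime_resolution_ns = meta$microtime_resolution_ns,
            irf_mean_ns = meta$irf_mean_ns,
            irf_sigma_ns = meta$irf_sigma_ns,
            duration_s = meta$duration_s)
}

#' Run the burst-analysis pipeline on a photon stream
#'
#' Sequences burst search, scoring, the filter cascade, the FRET histogram
#' and the per-state kinetics summaries; optionally the heavier PDA and fFCS
#' stages. Outputs are written under `out_dir` with the config hash and seed
#' embedded; identical inputs reproduce identical outputs.
#'
#' @param stream A `photon_stream` (or a container path).
#' @param cfg Config list from [load_config()].
#' @param out_dir Output directory (created if missing); `NULL` to skip
#'   writing.
#' @param stages Character subset of `c("bursts", "histogram", "lifetime",
#'   "pda", "ffcs")`.
#' @param pda_samples,pda_maxit Budget of the PDA stage.
#' @return Named list of stage results plus a `manifest`.
#' @export
run_pipeline <- function(stream, cfg = load_config(), out_dir = NULL,
                         stages = c("bursts", "histogram", "lifetime"),
                         pda_samples = 3e4, pda_maxit = 400) {
  if (is.character(stream)) stream <- read_photon_stream(stream)
  co <- do.call(correction_set, cfg$corrections)
  res <- list()
  spans <- apbs_search(stream, cfg$burst$window_ms, cfg$burst$min_counts,
                       cfg$burst$min_in_window)
  tab <- score_bursts(stream, spans, co, cfg$burst$alex2cde_tau_us)
  sel <- select_fret_bursts(tab, cfg$burst$s_range,
                            cfg$burst$alex2cde_max, cfg$burst$tdx_taa_max)
  res$bursts <- sel
  res$spans <- spans[spans$burst_id %in% sel$burst_id, ]
  counts <- c(searched = nrow(spans), selected = nrow(sel))

  if ("histogram" %in% stages)
    res$histogram <- fret_histogram(sel)
  if ("lifetime" %in% stages) {
    res$static_line <- static_fret_line(
      fret_constants(cfg$fret$R0_A, cfg$fret$tauD_ns,
                     linker_length = cfg$fret$linker_A))
  }
  scheme <- kinetic_scheme(
    matrix(1, 3, 3), cfg$fret$distances_A, cfg$fret$lifetimes_ns,
    names(cfg$fret$distances_A),
    fret_constants(cfg$fret$R0_A, cfg$fret$tauD_ns,
                   linker_length = cfg$fret$linker_A))
  if ("pda" %in% stages) {
    pm <- pda_model(scheme, sigma = cfg$fret$sigma, corrections = co,
                    bin_times_ms = cfg$pda$bin_times_ms,
                    grid_E = cfg$pda$grid_E,
                    min_photons = cfg$pda$min_photons)
    hist_list <- pda_prepare(stream, res$spans, pm)
    res$pda <- pda_robustness(hist_list, pm,
                              initial_values = cfg$pda$restart_values_ms,
                              bounds = cfg$pda$rate_bounds_ms,
                              n_samples = pda_samples, seed = cfg$seed,
                              maxit = pda_maxit)
  }
  if ("ffcs" %in% stages) {
    filt <- build_filters(stream, sel, res$spans,
                          cfg$ffcs$species_windows)
    curves <- correlate_filtered(stream, filt)
    res$ffcs <- fit_fcs_global(curves, cfg$ffcs$tau_diff_us, cfg$ffcs$rho)
    res$ffcs_curves <- curves
  }
  res$manifest <- list(config_hash = .config_hash(cfg), seed = cfg$seed,
                       counts = counts,
                       package_version =
                         as.character(utils::packageVersion("fretdyn")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_burst_table(sel, file.path(out_dir, "bursts.csv"))
    yaml::write_yaml(res$manifest, file.path(out_dir, "manifest.yaml"))
    writeLines(.pipeline_report(res), file.path(out_dir, "report.md"))
  }
  res
}

# markdown summary of a pipeline run
.pipeline_report <- function(res) {
  ln <- c("# Burst-analysis report", "",
          sprintf("- config hash: %s, seed: %s",
                  res$manifest$config_hash, res$manifest$seed),
          sprintf("- bursts: %d searched, %d selected",
                  res$manifest$counts["searched"],
                  res$manifest$counts["selected"]))
  if (!is.null(res$histogram))
    ln <- c(ln, sprintf("- FRET efficiency: mean %.3f, SD %.3f over %d bursts",
                        res$histogram$mean, res$histogram$sd,
                        res$histogram$n))
  if (!is.null(res$pda)) {
    ln <- c(ln, "", "## Dynamic PDA (restart-averaged)", "")
    r <- res$pda
    for (i in 1:3) for (j in 1:3) {
      if (i == j) next
      ln <- c(ln, sprintf("- k_%d,%d = %.2f +/- %.2f ms^-1", i, j,
                          r$rates_mean[i, j], r$rates_sd[i, j]))
    }
    ln <- c(ln, sprintf("- fractions (%%): %s",
                        paste(sprintf("%.1f", r$fractions_mean),
                              collapse = " / ")))
  }
  if (!is.null(res$ffcs))
    ln <- c(ln, "", "## fFCS", "",
            sprintf("- tau_R = %.1f +/- %.1f us (chi2/dof %.2f)",
                    res$ffcs$tau_R_us, res$ffcs$tau_R_se_us,
                    res$ffcs$chi2_reduced))
  ln
}

#' Rate-table report in the published layout
#'
#' Assembles fitted rates, state fractions and global chi-squared for one or
#' more variants into the standard 10-row layout: the six rates
#' `k_1,2 ... k_3,2`, the three state percentages, then the global
#' chi-squared, one column pair (value, sd) per variant.
#'
#' @param fits Named list of `pda_robust` objects (names become columns).
#' @return Data frame with a `quantity` column and `<variant>` /
#'   `<variant>_sd` columns.
#' @export
table1_report <- function(fits) {
  stopifnot(length(fits) >= 1L)
  qn <- c("k_1,2", "k_1,3", "k_2,1", "k_2,3", "k_3,1", "k_3,2",
          "pct_O1", "pct_O2", "pct_C", "chi2_global")
  out <- data.frame(quantity = qn)
  ij <- list(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1), c(3, 2))
  for (v in names(fits)) {
    f <- fits[[v]]
    vals <- c(vapply(ij, function(x) f$rates_mean[x[1], x[2]], numeric(1)),
              f$fractions_mean, mean(f$chi2_global))
    sds <- c(vapply(ij, function(x) f$rates_sd[x[1], x[2]], numeric(1)),
             f$fractions_sd, NA)
    out[[v]] <- vals
    out[[paste0(v, "_sd")]] <- sds
  }
  out
}

#' Parse a rate-table report back into per-variant values
#'
#' Inverse of [table1_report()]: returns the long format
#' `variant, quantity, value, sd`.
#'
#' @param report Data frame from [table1_report()] (or the same layout).
#' @return Long data frame.
#' @export
parse_table1_report <- function(report) {
  vars <- setdiff(names(report), "quantity")
  vars <- vars[!endsWith(vars, "_sd")]
  do.call(rbind, lapply(vars, function(v) {
    data.frame(variant = v, quantity = report$quantity,
               value = report[[v]],
               sd = if (paste0(v, "_sd") %in% names(report))
                 report[[paste0(v, "_sd")]] else NA_real_)
  }))
}
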