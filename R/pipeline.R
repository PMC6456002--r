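#' Run configuration for synthetic experiments and analyses
#'
#' Collects every knob of an end-to-end run: protocol, archetype population,
#' cell-to-cell variability, acquisition parameters, processing options and
#' classification threshold. All randomness derives from `seed`; there are
#' no wall-clock defaults, so a config reproduces its outputs exactly.
#'
#' @param protocol protocol name (see [make_protocol()]) or a
#'   [perfusion_protocol()].
#' @param protocol_params overrides passed to [make_protocol()].
#' @param archetypes character vector of archetype names (see
#'   [archetype()]).
#' @param n_per_archetype cells per archetype.
#' @param cv cell-to-cell variability (log-normal CV of rate parameters).
#' @param seed integer master seed.
#' @param compartment compartment measured (`"mito"` for the fingerprint).
#' @param acq an [acquisition_model()].
#' @param sensor optional [sensor_model()] override (default:
#'   per-compartment).
#' @param dt_out imaging cadence (s).
#' @param baseline_s normalization baseline length (s).
#' @param bleach_correct fit/divide an exponential bleach model on the
#'   baseline window (`"auto"` = only when the acquisition model bleaches).
#' @param tau classification threshold (normalized ratio units).
#' @param out_dir output directory (NULL = return results only).
#' @return Object of class `run_config` (a validated list).
#' @export
run_config <- function(protocol = "glc_removal_then_oligo",
                       protocol_params = list(),
                       archetypes = "hela_like", n_per_archetype = 10,
                       cv = 0.3, seed = 1L, compartment = "mito",
                       acq = acquisition_model(noise_sd = 2),
                       sensor = NULL, dt_out = 1, baseline_s = 60,
                       bleach_correct = "auto", tau = 0.1, out_dir = NULL) {
  if (!inherits(protocol, "perfusion_protocol"))
    protocol <- make_protocol(protocol, protocol_params)
  if (n_per_archetype < 1) stop("n_per_archetype must be >= 1")
  if (!is.numeric(seed) || length(seed) != 1)
    stop("seed must be a single integer (explicit, no wall-clock default)")
  for (a in archetypes) archetype(a)  # resolvable?
  structure(list(protocol = protocol, archetypes = archetypes,
                 n_per_archetype = as.integer(n_per_archetype), cv = cv,
                 seed = as.integer(seed), compartment = compartment,
                 acq = acq, sensor = sensor, dt_out = dt_out,
                 baseline_s = baseline_s, bleach_correct = bleach_correct,
                 tau = tau, out_dir = out_dir),
            class = "run_config")
}

config_hash <- function(config) rlang::hash(unclass(config))

quiescent_windows_for <- function(config) {
  w <- protocol_windows(config$protocol, baseline_s = config$baseline_s)
  list(w$baseline)
}

should_bleach_correct <- function(config) {
  if (identical(config$bleach_correct, "auto"))
    config$acq$bleach_rate_donor > 0 || config$acq$bleach_rate_acceptor > 0
  else isTRUE(config$bleach_correct)
}

process_one <- function(trace, config) {
  w <- protocol_windows(config$protocol, baseline_s = config$baseline_s)
  qw <- if (should_bleach_correct(config)) quiescent_windows_for(config)
        else NULL
  process_trace(trace, baseline_window = w$baseline, quiescent_windows = qw)
}

# noise SD of the normalized trace, estimated from baseline residuals
estimate_noise_sd <- function(rt, baseline_window) {
  sel <- in_window(rt$time, baseline_window) & rt$valid
  if (sum(sel) < 3) return(0)
  stats::sd(rt$ratio[sel])
}

#' Run a full synthetic experiment
#'
#' Simulates an archetype population through the configured perfusion
#' protocol, renders dual-channel traces with the acquisition model,
#' processes them (background subtraction, ratio, optional bleach
#' correction, normalization), extracts per-cell features, builds the
#' metabolic fingerprint, classifies each cell, and computes group
#' statistics. Deterministic for a fixed config.
#'
#' @param config a [run_config()].
#' @return Object of class `results_bundle`: list with `traces` (processed
#'   `ratio_trace`s), `features`, `fingerprint`, `labels` (classification),
#'   `generating` (true archetype of each cell), `stats`, `config`,
#'   `config_hash`, `version`.
#' @export
run_synthetic_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  protocol <- config$protocol
  w <- protocol_windows(protocol, baseline_s = config$baseline_s)

  pops <- list()
  for (i in seq_along(config$archetypes)) {
    nm <- config$archetypes[i]
    pops[[nm]] <- sample_population(archetype(nm), config$n_per_archetype,
                                    cv = config$cv,
                                    seed = config$seed + 1000L * i)
  }

  traces <- list(); feats <- list(); gen <- character()
  idx <- 0L
  for (nm in names(pops)) {
    for (arch in pops[[nm]]) {
      idx <- idx + 1L
      sim <- simulate_cell(arch, protocol, dt_out = config$dt_out)
      tr <- render_trace(sim, config$compartment, sensor = config$sensor,
                         acq = config$acq, seed = config$seed + idx,
                         cell_id = sprintf("%s_%03d", nm, idx))
      rt <- process_one(tr, config)
      nse <- estimate_noise_sd(rt, w$baseline)
      fe <- extract_features(rt, protocol, noise_sd_est = nse,
                             baseline_s = config$baseline_s)
      traces[[idx]] <- rt
      feats[[idx]] <- fe
      gen[idx] <- nm
    }
  }
  features <- do.call(rbind, feats)

  fp <- NULL; labels <- NULL; stats_out <- list()
  if (all(is.finite(features$delta_oligo))) {
    fp <- build_fingerprint(features, groups = gen)
    labels <- classify_setting(fp, tau = config$tau)
    truth <- archetype_class(fp$points$group)
    comparable <- truth != "unknown"
    agreement <- if (any(comparable))
      mean(labels[comparable] == truth[comparable]) else NA_real_
    stats_out$classification_agreement <- agreement
    if (length(unique(gen)) >= 2) {
      stats_out$delta_oligo_test <- compare_groups(
        split(fp$points$delta_oligo, fp$points$group))
      stats_out$delta_glc_test <- compare_groups(
        split(fp$points$delta_glc, fp$points$group))
    }
  }

  bundle <- structure(
    list(traces = traces, features = features, fingerprint = fp,
         labels = labels, generating = gen, stats = stats_out,
         config = config, config_hash = config_hash(config),
         version = as.character(utils::packageVersion("atpfret"))),
    class = "results_bundle")
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

# expected classification for a named archetype population
archetype_class <- function(names) {
  glyc <- c("hela_like", "mef_young_like")
  oxid <- c("beta_like", "mef_old_like", "mfn2_ko_like")
  ifelse(names %in% glyc, "glycolytic",
         ifelse(names %in% oxid, "oxidative", "unknown"))
}

#' Run the analysis chain on externally supplied traces
#'
#' The same processing, feature-extraction and fingerprint stages as
#' [run_synthetic_experiment()], but starting from measured dual-channel
#' traces (a list of [dual_channel_trace()] or a trace CSV path) and a
#' perfusion protocol describing the recording.
#'
#' @param traces list of `dual_channel_trace` or a path to a trace CSV (see
#'   [read_traces_csv()]).
#' @param protocol a [perfusion_protocol()] or a protocol YAML path; must
#'   cover the recording duration.
#' @param config a [run_config()] (protocol/population fields are ignored).
#' @return A `results_bundle` (without simulation ground truth).
#' @export
run_analysis <- function(traces, protocol, config = run_config()) {
  if (is.character(traces)) traces <- read_traces_csv(traces)
  if (is.character(protocol)) protocol <- read_protocol(protocol)
  stopifnot(inherits(protocol, "perfusion_protocol"))
  config$protocol <- protocol
  t_max <- max(vapply(traces, function(tr) max(tr$time), numeric(1)))
  if (protocol$total_duration < t_max - 1e-9)
    stop("protocol shorter than recording (",
         protocol$total_duration, " s < ", t_max, " s)")
  w <- protocol_windows(protocol, baseline_s = config$baseline_s)
  out_tr <- list(); feats <- list()
  for (i in seq_along(traces)) {
    rt <- process_one(traces[[i]], config)
    nse <- estimate_noise_sd(rt, w$baseline)
    feats[[i]] <- extract_features(rt, protocol, noise_sd_est = nse,
                                   baseline_s = config$baseline_s)
    out_tr[[i]] <- rt
  }
  features <- do.call(rbind, feats)
  fp <- NULL; labels <- NULL
  if (all(is.finite(features$delta_oligo))) {
    fp <- build_fingerprint(features)
    labels <- classify_setting(fp, tau = config$tau)
  }
  bundle <- structure(
    list(traces = out_tr, features = features, fingerprint = fp,
         labels = labels, generating = NULL, stats = list(),
         config = config, config_hash = config_hash(config),
         version = as.character(utils::packageVersion("atpfret"))),
    class = "results_bundle")
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

#' Write a results bundle to disk
#'
#' Writes processed traces, the features table, fingerprint points, group
#' summary and run statistics, all stamped with the config hash and a
#' format version.
#'
#' @param bundle a `results_bundle`.
#' @param dir output directory (created if missing).
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long <- do.call(rbind, lapply(bundle$traces, function(rt)
    data.frame(time_s = rt$time, cell_id = attr(rt, "cell_id"),
               ratio = rt$ratio, valid = rt$valid,
               stringsAsFactors = FALSE)))
  con <- file(file.path(dir, "processed_traces.csv"), "w")
  writeLines(sprintf(
    "# atpfret processed traces format_version=1 config_hash=%s",
    bundle$config_hash), con)
  utils::write.csv(long, con, row.names = FALSE)
  close(con)
  write_features_csv(bundle$features, file.path(dir, "features.csv"),
                     config_hash = bundle$config_hash)
  if (!is.null(bundle$fingerprint)) {
    write_fingerprint_csv(bundle$fingerprint,
                          file.path(dir, "fingerprint.csv"))
    write_group_summary_json(bundle$fingerprint,
                             file.path(dir, "group_summary.json"))
  }
  jsonlite::write_json(
    list(format_version = 1L, config_hash = bundle$config_hash,
         version = bundle$version, stats = bundle$stats,
         labels = bundle$labels),
    file.path(dir, "stats.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  invisible(dir)
}

#' Trace CSV I/O
#'
#' Wide per-frame format with required columns `time_s`, `cell_id`,
#' `compartment`, `cfp`, `yfp`, `bg_cfp`, `bg_yfp` (UTF-8, comma-separated,
#' `.` decimal; intensities in arbitrary counts, time in seconds). A
#' `# atpfret ...` comment header carries the format version.
#'
#' @param traces list of [dual_channel_trace()].
#' @param path file path.
#' @return `read_traces_csv` returns a list of `dual_channel_trace`.
#' @export
write_traces_csv <- function(traces, path) {
  long <- do.call(rbind, lapply(traces, function(tr)
    data.frame(time_s = tr$time, cell_id = attr(tr, "cell_id"),
               compartment = attr(tr, "compartment"),
               cfp = tr$cfp, yfp = tr$yfp,
               bg_cfp = tr$bg_cfp_est, bg_yfp = tr$bg_yfp_est,
               stringsAsFactors = FALSE)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# atpfret traces format_version=1", con)
  utils::write.csv(long, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("time_s", "cell_id", "compartment", "cfp", "yfp",
            "bg_cfp", "bg_yfp")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trace CSV schema violation: missing column(s) ",
         paste(miss, collapse = ", "))
  lapply(split(df, df$cell_id), function(d) {
    d <- d[order(d$time_s), ]
    dual_channel_trace(time = d$time_s, cfp = d$cfp, yfp = d$yfp,
                       bg_cfp_est = d$bg_cfp, bg_yfp_est = d$bg_yfp,
                       cell_id = as.character(d$cell_id[1]),
                       compartment = as.character(d$compartment[1]))
  })
}

#' Scatter plot of a metabolic fingerprint
#'
#' One point per cell with mean +/- SD crosshairs per group, mirroring the
#' standard presentation of the two-axis fingerprint.
#'
#' @param fp a `fingerprint_table`.
#' @param ... passed to [plot()].
#' @export
plot_fingerprint <- function(fp, ...) {
  pts <- fp$points
  grp <- factor(pts$group)
  cols <- seq_along(levels(grp)) + 1
  graphics::plot(pts$delta_glc, pts$delta_oligo, col = cols[grp], pch = 16,
                 xlab = expression(Delta ~ "glucose removal (norm. ratio)"),
                 ylab = expression(Delta ~ "oligomycin (norm. ratio)"), ...)
  graphics::abline(h = 0, v = 0, col = "grey70", lty = 3)
  for (i in seq_along(levels(grp))) {
    g <- pts[grp == levels(grp)[i], ]
    mx <- mean(g$delta_glc); my <- mean(g$delta_oligo)
    sx <- stats::sd(g$delta_glc); sy <- stats::sd(g$delta_oligo)
    graphics::segments(mx - sx, my, mx + sx, my, col = cols[i], lwd = 2)
    graphics::segments(mx, my - sy, mx, my + sy, col = cols[i], lwd = 2)
    graphics::points(mx, my, pch = 3, cex = 1.5, col = cols[i])
  }
  graphics::legend("bottomleft", legend = levels(grp), col = cols, pch = 16,
                   bty = "n")
  invisible(fp)
}
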