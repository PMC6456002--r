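#' Per-cell scalar features of a processed ratio trace
#'
#' These operations compute the summaries reported per cell: basal level,
#' transient peak amplitude, onset of decrease, depletion minimum, maximal
#' signed change, and peak width (FWHM). All of them ignore frames flagged
#' invalid.
#'
#' @name trace_features
NULL

valid_in_window <- function(rt, window) {
  sel <- in_window(rt$time, window) & rt$valid
  if (!any(sel)) stop("window contains no valid frames")
  sel
}

#' @rdname trace_features
#' @param rt a `ratio_trace`.
#' @param window `c(t0, t1)` pre-stimulus window with >= 3 valid frames.
#' @return `basal_level`: mean ratio over the window.
#' @export
basal_level <- function(rt, window) {
  sel <- in_window(rt$time, window) & rt$valid
  if (sum(sel) < 3) stop("basal_level: need >= 3 valid frames")
  mean(rt$ratio[sel])
}

#' @rdname trace_features
#' @param stimulus_window `c(t0, t1)`: search window starting at the
#'   stimulus.
#' @param basal basal level (from [basal_level()]).
#' @param onset optional onset time; when given, the peak search ends at the
#'   earlier of the window end and the onset of decrease.
#' @return `peak_amplitude`: `max(ratio) - basal`, floored at 0.
#' @export
peak_amplitude <- function(rt, stimulus_window, basal, onset = NULL) {
  w <- stimulus_window
  if (!is.null(onset) && is.finite(onset)) w[2] <- min(w[2], onset)
  sel <- in_window(rt$time, w) & rt$valid
  if (!any(sel)) stop("peak_amplitude: empty window")
  max(max(rt$ratio[sel]) - basal, 0)
}

#' @rdname trace_features
#' @param stimulus_time time of the stimulus (s).
#' @param noise_sd_est estimated noise SD of the normalized trace.
#' @param threshold_sd,persist_frames onset rule parameters: the trace must
#'   fall below `1 - max(threshold_sd * noise_sd_est, min_drop)` and stay
#'   below for `persist_frames` consecutive valid frames.
#' @param min_drop minimum drop regardless of the noise estimate.
#' @return `onset_time`: first time the rule fires, or `NA` if never.
#' @export
onset_time <- function(rt, stimulus_time, noise_sd_est = 0,
                       threshold_sd = 3, persist_frames = 3,
                       min_drop = 0.01) {
  if (!isTRUE(attr(rt, "normalized")))
    stop("onset_time: trace must be normalized")
  thr <- 1 - max(threshold_sd * noise_sd_est, min_drop)
  idx <- which(rt$time >= stimulus_time & rt$valid)
  below <- rt$ratio[idx] < thr
  n <- length(below)
  if (n < persist_frames) return(NA_real_)
  for (i in seq_len(n - persist_frames + 1)) {
    if (all(below[i:(i + persist_frames - 1)]))
      return(as.numeric(rt$time[idx[i]]))
  }
  NA_real_
}

#' @rdname trace_features
#' @return `depletion_minimum`: minimum ratio over valid frames in the
#'   window.
#' @export
depletion_minimum <- function(rt, window) {
  sel <- valid_in_window(rt, window)
  min(rt$ratio[sel])
}

#' @rdname trace_features
#' @param baseline_window window whose mean is the reference level; must
#'   precede `window`.
#' @return `max_change`: the signed excursion of largest magnitude,
#'   `ratio[argmax |ratio - baseline|] - baseline`.
#' @export
max_change <- function(rt, window, baseline_window) {
  if (baseline_window[2] > window[1] + 1e-9)
    stop("max_change: baseline_window must precede window")
  bsel <- in_window(rt$time, baseline_window) & rt$valid
  if (!any(bsel)) stop("max_change: empty baseline window")
  b <- mean(rt$ratio[bsel])
  sel <- valid_in_window(rt, window)
  x <- rt$ratio[sel]
  x[which.max(abs(x - b))] - b
}

#' @rdname trace_features
#' @param frac width threshold as a fraction of the peak amplitude (0.5 =
#'   full width at half maximum).
#' @return `peak_width`: time between the first upward and last downward
#'   crossing of `basal + frac * amplitude`, linearly interpolated; `NA`
#'   when the amplitude is 0.
#' @export
peak_width <- function(rt, stimulus_window, basal, frac = 0.5) {
  sel <- valid_in_window(rt, stimulus_window)
  t <- rt$time[sel]; x <- rt$ratio[sel]
  amp <- max(x) - basal
  if (amp <= 0) return(NA_real_)
  level <- basal + frac * amp
  above <- x >= level
  if (!any(above)) return(NA_real_)
  i1 <- which(above)[1]
  i2 <- max(which(above))
  # linear interpolation to the crossing on each side
  t_up <- if (i1 == 1) t[1] else {
    t[i1 - 1] + (level - x[i1 - 1]) / (x[i1] - x[i1 - 1]) * (t[i1] - t[i1 - 1])
  }
  t_dn <- if (i2 == length(x)) t[i2] else {
    t[i2] + (x[i2] - level) / (x[i2] - x[i2 + 1]) * (t[i2 + 1] - t[i2])
  }
  t_dn - t_up
}

#' Extract the full feature set for one cell
#'
#' Applies the feature operations using the analysis windows implied by the
#' perfusion protocol: basal over the pre-stimulus baseline, peak/onset/
#' minimum over the first hexose-removal (or substitution) window, and the
#' fingerprint axes `delta_glc` (maximal signed change after hexose removal
#' or substitution) and `delta_oligo` (maximal signed change after
#' oligomycin onset, relative to the 60 s immediately before it). A cell
#' with more than `max_invalid_frac` invalid frames in any analysis window
#' is QC-failed.
#'
#' @param rt a normalized `ratio_trace`.
#' @param protocol the [perfusion_protocol()] of the recording.
#' @param noise_sd_est noise SD estimate for the onset rule.
#' @param baseline_s baseline window length (s).
#' @param max_invalid_frac QC threshold on the invalid-frame fraction.
#' @return A one-row data.frame (class `cell_features`).
#' @export
extract_features <- function(rt, protocol, noise_sd_est = 0,
                             baseline_s = 60, max_invalid_frac = 0.2) {
  stopifnot(inherits(rt, "ratio_trace"),
            inherits(protocol, "perfusion_protocol"))
  if (!isTRUE(attr(rt, "normalized")))
    stop("extract_features: trace must be normalized")
  w <- protocol_windows(protocol, baseline_s = baseline_s)
  stim_w <- if (!is.null(w$glc_removal)) w$glc_removal else w$substitution
  if (is.null(stim_w)) stop("protocol has no hexose removal or substitution")

  qc <- character()
  for (nm in names(w)) {
    sel <- in_window(rt$time, w[[nm]])
    if (any(sel) && mean(!rt$valid[sel]) > max_invalid_frac)
      qc <- c(qc, paste0("invalid_frames_", nm))
  }

  basal <- basal_level(rt, w$baseline)
  onset <- onset_time(rt, stim_w[1], noise_sd_est = noise_sd_est)
  peak <- peak_amplitude(rt, stim_w, basal, onset = onset)
  minv <- depletion_minimum(rt, stim_w)
  d_glc <- max_change(rt, stim_w, w$baseline)
  width <- peak_width(rt, stim_w, basal)

  d_ol <- NA_real_
  if (!is.null(w$oligo)) {
    pre <- c(max(0, w$oligo[1] - 60), w$oligo[1])
    d_ol <- max_change(rt, w$oligo, pre)
  }

  structure(data.frame(
    cell_id = attr(rt, "cell_id"), compartment = attr(rt, "compartment"),
    basal = basal, peak_amp = peak, onset_time = onset, min_level = minv,
    delta_glc = d_glc, delta_oligo = d_ol, peak_width = width,
    qc_pass = length(qc) == 0,
    qc_flags = paste(qc, collapse = ";"),
    stringsAsFactors = FALSE),
    class = c("cell_features", "data.frame"))
}

#' Write a features table as CSV (with format-version header)
#'
#' @param features data.frame of stacked [extract_features()] rows.
#' @param path output file.
#' @param config_hash optional configuration hash recorded in the header.
#' @export
write_features_csv <- function(features, path, config_hash = NA_character_) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# atpfret features format_version=1 config_hash=%s",
                     config_hash), con)
  utils::write.csv(features, con, row.names = FALSE)
  invisible(path)
}
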