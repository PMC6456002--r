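#' Dual-channel intensity trace
#'
#' Container for a single cell's CFP/YFP intensity time series with
#' background estimates, a per-frame validity flag and an append-only
#' provenance record of the processing steps applied.
#'
#' @param time time stamps (s), strictly increasing.
#' @param cfp,yfp channel intensities (counts).
#' @param bg_cfp_est,bg_yfp_est background estimates: scalars or per-frame
#'   vectors (counts).
#' @param cell_id cell identifier.
#' @param compartment `"cyto"`, `"mito"` or `"er"`.
#' @param valid per-frame logical flag.
#' @param sensor,acq optional models carried for round-trip validation.
#' @return Object of class `dual_channel_trace`.
#' @export
dual_channel_trace <- function(time, cfp, yfp, bg_cfp_est = NA_real_,
                               bg_yfp_est = NA_real_, cell_id = "cell_1",
                               compartment = "mito",
                               valid = rep(TRUE, length(time)),
                               sensor = NULL, acq = NULL) {
  n <- length(time)
  stopifnot(length(cfp) == n, length(yfp) == n, length(valid) == n)
  if (n > 1 && any(diff(time) <= 0)) stop("time must be strictly increasing")
  df <- data.frame(time = time, cfp = cfp, yfp = yfp,
                   bg_cfp_est = bg_cfp_est, bg_yfp_est = bg_yfp_est,
                   valid = valid)
  structure(df, cell_id = cell_id, compartment = compartment,
            provenance = character(), sensor = sensor, acq = acq,
            class = c("dual_channel_trace", "data.frame"))
}

provenance <- function(x) attr(x, "provenance")

append_provenance <- function(x, step) {
  attr(x, "provenance") <- c(attr(x, "provenance"), step)
  x
}

#' Subtract channel backgrounds
#'
#' Subtracts the respective background signal from each channel. Frames in
#' which either corrected channel is non-positive are flagged invalid rather
#' than clipped, so degenerate frames propagate visibly instead of producing
#' spurious ratios.
#'
#' @param trace a [dual_channel_trace()].
#' @param bg_cfp,bg_yfp backgrounds (counts); default: the estimates stored
#'   in the trace.
#' @return The corrected `dual_channel_trace` with updated provenance.
#' @export
subtract_background <- function(trace, bg_cfp = NULL, bg_yfp = NULL) {
  stopifnot(inherits(trace, "dual_channel_trace"))
  if (is.null(bg_cfp)) bg_cfp <- trace$bg_cfp_est
  if (is.null(bg_yfp)) bg_yfp <- trace$bg_yfp_est
  if (any(is.na(bg_cfp)) || any(is.na(bg_yfp)))
    stop("no background available: trace carries no estimate and none given")
  if (any(bg_cfp < 0) || any(bg_yfp < 0)) stop("backgrounds must be >= 0")
  trace$cfp <- trace$cfp - bg_cfp
  trace$yfp <- trace$yfp - bg_yfp
  trace$valid <- trace$valid & trace$cfp > 0 & trace$yfp > 0
  append_provenance(trace, "background_subtracted")
}

#' Ratio trace
#'
#' The YFP/CFP ratio time series derived from a background-subtracted
#' dual-channel trace, with validity flags and processing provenance.
#'
#' @param trace a background-subtracted [dual_channel_trace()].
#' @return Object of class `ratio_trace`: data.frame with columns `time`,
#'   `ratio`, `valid`.
#' @export
compute_ratio <- function(trace) {
  stopifnot(inherits(trace, "dual_channel_trace"))
  if (!"background_subtracted" %in% provenance(trace))
    stop("compute_ratio: background must be subtracted first")
  ratio <- ifelse(trace$valid, trace$yfp / trace$cfp, NA_real_)
  df <- data.frame(time = trace$time, ratio = ratio, valid = trace$valid)
  structure(df, cell_id = attr(trace, "cell_id"),
            compartment = attr(trace, "compartment"),
            provenance = c(provenance(trace), "ratio_computed"),
            normalized = FALSE, baseline_window = NULL, baseline_mean = NULL,
            bleach_fit = NULL, sensor = attr(trace, "sensor"),
            acq = attr(trace, "acq"),
            class = c("ratio_trace", "data.frame"))
}

in_window <- function(time, window) time >= window[1] & time <= window[2]

in_windows <- function(time, windows) {
  if (is.numeric(windows)) windows <- list(windows)
  Reduce(`|`, lapply(windows, function(w) in_window(time, w)))
}

#' Photobleach correction by exponential curve fitting
#'
#' Fits `r(t) = A * exp(-k * t)` (k >= 0) by nonlinear least squares to the
#' ratio over stimulus-free (quiescent) windows, then divides the whole
#' trace by `exp(-k * t)`, preserving the amplitude at t = 0. A fitted decay
#' below `k_floor` is treated as no bleaching and the trace is returned
#' unchanged (apart from provenance).
#'
#' @param rt a [compute_ratio()] output (not yet normalized).
#' @param quiescent_windows list of `c(t0, t1)` windows known to be free of
#'   stimulus responses; must jointly contain at least 10 valid frames.
#' @param k_floor decay-rate floor (1/s) below which no correction is made.
#' @return The corrected `ratio_trace`; the fit is stored in
#'   `attr(, "bleach_fit")` (elements `A`, `k`, `corrected`).
#' @export
correct_bleach <- function(rt, quiescent_windows, k_floor = 1e-6) {
  stopifnot(inherits(rt, "ratio_trace"))
  if (isTRUE(attr(rt, "normalized")))
    stop("correct_bleach must run before normalization")
  sel <- in_windows(rt$time, quiescent_windows) & rt$valid
  if (sum(sel) < 10)
    stop("correct_bleach: need >= 10 valid frames in quiescent windows")
  t <- rt$time[sel]; r <- rt$ratio[sel]
  # log-linear start values, then bounded Levenberg-Marquardt
  lf <- stats::lm(log(r) ~ t)
  start <- list(A = exp(stats::coef(lf)[[1]]),
                k = max(-stats::coef(lf)[[2]], 0))
  if (start$k < k_floor) {
    # flat or rising trace: no decay to correct
    attr(rt, "bleach_fit") <- list(A = start$A, k = start$k,
                                   corrected = FALSE)
    attr(rt, "provenance") <- c(provenance(rt), "bleach_corrected")
    return(rt)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(r ~ A * exp(-k * t), start = start,
                      lower = c(A = 0, k = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("correct_bleach: fit failed: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  corrected <- cf[["k"]] >= k_floor
  if (corrected) rt$ratio <- rt$ratio / exp(-cf[["k"]] * rt$time)
  attr(rt, "bleach_fit") <- list(A = cf[["A"]], k = cf[["k"]],
                                 corrected = corrected)
  attr(rt, "provenance") <- c(provenance(rt), "bleach_corrected")
  rt
}

#' Per-channel photobleach correction
#'
#' Variant that fits a mono-exponential decay to each channel separately
#' over the quiescent windows and divides the channels before the ratio is
#' formed; an alternative to the default ratio-level correction.
#'
#' @param trace a background-subtracted [dual_channel_trace()].
#' @inheritParams correct_bleach
#' @return The corrected `dual_channel_trace`.
#' @export
correct_bleach_channels <- function(trace, quiescent_windows, k_floor = 1e-6) {
  stopifnot(inherits(trace, "dual_channel_trace"))
  if (!"background_subtracted" %in% provenance(trace))
    stop("background must be subtracted first")
  sel <- in_windows(trace$time, quiescent_windows) & trace$valid
  if (sum(sel) < 10) stop("need >= 10 valid frames in quiescent windows")
  fit1 <- function(y) {
    t <- trace$time[sel]
    lf <- stats::lm(log(y[sel]) ~ t)
    fit <- minpack.lm::nlsLM(y[sel] ~ A * exp(-k * t),
                             start = list(A = exp(stats::coef(lf)[[1]]),
                                          k = max(-stats::coef(lf)[[2]], 0)),
                             lower = c(A = 0, k = 0))
    stats::coef(fit)[["k"]]
  }
  k_c <- fit1(trace$cfp); k_y <- fit1(trace$yfp)
  if (k_c >= k_floor) trace$cfp <- trace$cfp / exp(-k_c * trace$time)
  if (k_y >= k_floor) trace$yfp <- trace$yfp / exp(-k_y * trace$time)
  attr(trace, "bleach_fit") <- list(k_cfp = k_c, k_yfp = k_y)
  append_provenance(trace, "bleach_corrected_channels")
}

#' Normalize a ratio trace to its pre-stimulus baseline
#'
#' Divides the ratio by its mean over the baseline window, so the baseline
#' sits at 1 and responses read as fractional changes.
#'
#' @param rt a `ratio_trace`.
#' @param baseline_window `c(t0, t1)` containing >= 3 valid frames; by
#'   convention the final stretch before the first stimulus.
#' @return The normalized `ratio_trace` (`attr(, "normalized")` is TRUE and
#'   `attr(, "baseline_mean")` stores the divisor).
#' @export
normalize_trace <- function(rt, baseline_window) {
  stopifnot(inherits(rt, "ratio_trace"))
  sel <- in_window(rt$time, baseline_window) & rt$valid
  if (sum(sel) < 3)
    stop("normalize_trace: need >= 3 valid frames in baseline window")
  b <- mean(rt$ratio[sel])
  rt$ratio <- rt$ratio / b
  attr(rt, "normalized") <- TRUE
  attr(rt, "baseline_window") <- baseline_window
  attr(rt, "baseline_mean") <- b
  attr(rt, "provenance") <- c(provenance(rt), "normalized")
  rt
}

#' Standard processing chain
#'
#' Background subtraction, ratio, optional bleach correction on quiescent
#' windows, and baseline normalization, in the enforced order.
#'
#' @param trace a [dual_channel_trace()].
#' @param baseline_window normalization window `c(t0, t1)`.
#' @param quiescent_windows windows for [correct_bleach()]; NULL skips the
#'   bleach correction step.
#' @inheritParams subtract_background
#' @return A normalized `ratio_trace`.
#' @export
process_trace <- function(trace, baseline_window, quiescent_windows = NULL,
                          bg_cfp = NULL, bg_yfp = NULL) {
  rt <- compute_ratio(subtract_background(trace, bg_cfp, bg_yfp))
  if (!is.null(quiescent_windows)) rt <- correct_bleach(rt, quiescent_windows)
  normalize_trace(rt, baseline_window)
}
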