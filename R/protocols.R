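#' Perfusion protocols
#'
#' A perfusion protocol is the timeline of buffer segments a cell experiences
#' on the microscope stage: which hexose (if any) is present, at what
#' concentration, and whether the ATP-synthase inhibitor oligomycin or the
#' complex-III inhibitor antimycin A is in the bath. The same object drives
#' both the bioenergetics simulation and the choice of analysis windows.
#'
#' @param segments data.frame with columns `t_start`, `t_end` (seconds),
#'   `hexose` (one of `"glucose"`, `"mannose"`, `"dg2"`, `"none"`),
#'   `hexose_conc` (mM), `oligomycin`, `antimycin` (logical). Segments must
#'   be contiguous, non-overlapping and strictly increasing, covering
#'   `[0, total_duration]`.
#' @param drug_conc named numeric metadata (e.g. `oligomycin_uM`,
#'   `antimycin_uM`); informational only, the model treats drugs as flags.
#' @return An object of class `perfusion_protocol`.
#' @export
perfusion_protocol <- function(segments,
                               drug_conc = c(oligomycin_uM = 2, antimycin_uM = 2.5)) {
  stopifnot(is.data.frame(segments))
  need <- c("t_start", "t_end", "hexose", "hexose_conc", "oligomycin", "antimycin")
  miss <- setdiff(need, names(segments))
  if (length(miss))
    stop("protocol segments missing columns: ", paste(miss, collapse = ", "))
  segments <- segments[need]
  segments$hexose <- as.character(segments$hexose)
  bad <- setdiff(segments$hexose, c("glucose", "mannose", "dg2", "none"))
  if (length(bad)) stop("unknown hexose: ", paste(bad, collapse = ", "))
  if (any(segments$hexose_conc < 0)) stop("hexose_conc must be >= 0")
  if (any(segments$hexose == "none" & segments$hexose_conc != 0))
    stop("hexose = none implies hexose_conc = 0")
  if (any(segments$hexose != "none" & segments$hexose_conc <= 0))
    stop("hexose segments need hexose_conc > 0")
  n <- nrow(segments)
  if (n < 1L) stop("protocol needs at least one segment")
  if (segments$t_start[1] != 0) stop("first segment must start at t = 0")
  if (any(segments$t_end <= segments$t_start))
    stop("segments must have t_end > t_start")
  if (n > 1L && any(abs(segments$t_start[-1] - segments$t_end[-n]) > 1e-9))
    stop("segments must be contiguous")
  structure(
    list(segments = segments,
         total_duration = segments$t_end[n],
         drug_conc = drug_conc),
    class = "perfusion_protocol")
}

#' @export
print.perfusion_protocol <- function(x, ...) {
  cat("<perfusion_protocol> ", nrow(x$segments), " segments, ",
      x$total_duration, " s total\n", sep = "")
  print(x$segments, row.names = FALSE)
  invisible(x)
}

# index of the segment active at time t (right-open intervals; t = end maps
# to the last segment)
segment_index_at <- function(protocol, t) {
  s <- protocol$segments
  i <- findInterval(t, s$t_start)
  pmin(pmax(i, 1L), nrow(s))
}

#' Build a named perfusion protocol
#'
#' Constructs the standard stimulation timelines used throughout the package:
#' glucose removal (with or without readdition), substitution of glucose by
#' 2-deoxyglucose or mannose, mannose withdrawal with or without oligomycin,
#' three successive glucose depletions, and the two-phase fingerprint
#' protocols combining glucose removal and oligomycin.
#'
#' All protocols start from a baseline of 10 mM glucose. Durations (seconds)
#' can be overridden through `params`; available keys depend on the protocol
#' and default to: `baseline_s = 300`, `removal_s = 1500`, `readd_s = 120`,
#' `substitute_s = 600`, `withdraw_s = 600`, `oligo_s = 600`,
#' `hexose_conc = 10`. `params$antimycin = TRUE` adds antimycin A to every
#' oligomycin-containing segment.
#'
#' @param name one of `"glucose_removal"`, `"glucose_removal_readd"`,
#'   `"dg2_substitution"`, `"mannose_switch"`, `"mannose_switch_oligo"`,
#'   `"repeated_depletion"`, `"oligo_then_glc_removal"`,
#'   `"glc_removal_then_oligo"`.
#' @param params named list of overrides (see Details).
#' @return A [perfusion_protocol()].
#' @export
make_protocol <- function(name, params = list()) {
  name <- match.arg(name, c(
    "glucose_removal", "glucose_removal_readd", "dg2_substitution",
    "mannose_switch", "mannose_switch_oligo", "repeated_depletion",
    "oligo_then_glc_removal", "glc_removal_then_oligo"))
  p <- list(baseline_s = 300, removal_s = 1500, readd_s = 120,
            substitute_s = 600, withdraw_s = 600, oligo_s = 600,
            hexose_conc = 10, antimycin = FALSE)
  unknown <- setdiff(names(params), names(p))
  if (length(unknown))
    stop("unknown protocol override(s): ", paste(unknown, collapse = ", "))
  p[names(params)] <- params
  gc10 <- p$hexose_conc
  anti <- isTRUE(p$antimycin)

  seg <- function(dur, hexose, conc, oligo = FALSE, antim = FALSE) {
    data.frame(t_start = NA_real_, t_end = dur, hexose = hexose,
               hexose_conc = conc, oligomycin = oligo, antimycin = antim,
               stringsAsFactors = FALSE)
  }
  segs <- switch(name,
    glucose_removal = rbind(
      seg(p$baseline_s, "glucose", gc10),
      seg(p$removal_s, "none", 0)),
    glucose_removal_readd = rbind(
      seg(p$baseline_s, "glucose", gc10),
      seg(p$removal_s, "none", 0),
      seg(p$readd_s, "glucose", gc10)),
    dg2_substitution = rbind(
      seg(p$baseline_s, "glucose", gc10),
      seg(p$substitute_s, "dg2", gc10)),
    mannose_switch = rbind(
      seg(p$baseline_s, "glucose", gc10),
      seg(p$substitute_s, "mannose", gc10),
      seg(p$withdraw_s, "none", 0)),
    mannose_switch_oligo = rbind(
      seg(p$baseline_s, "glucose", gc10),
      seg(p$substitute_s * 2 / 3, "mannose", gc10),
      seg(p$substitute_s / 3, "mannose", gc10, TRUE, anti),
      seg(p$withdraw_s, "none", 0, TRUE, anti)),
    repeated_depletion = rbind(
      seg(p$baseline_s, "glucose", gc10),
      seg(p$removal_s / 2, "none", 0),
      seg(p$readd_s, "glucose", gc10),
      seg(p$removal_s / 2, "none", 0),
      seg(p$readd_s, "glucose", gc10),
      seg(p$removal_s / 2, "none", 0)),
    oligo_then_glc_removal = rbind(
      seg(p$baseline_s, "glucose", gc10),
      seg(p$oligo_s / 2, "glucose", gc10, TRUE, anti),
      seg(p$removal_s, "none", 0, TRUE, anti)),
    glc_removal_then_oligo = rbind(
      seg(p$baseline_s, "glucose", gc10),
      seg(p$removal_s, "none", 0),
      seg(p$oligo_s, "none", 0, TRUE, anti)))

  segs$t_end <- cumsum(segs$t_end)
  segs$t_start <- c(0, segs$t_end[-nrow(segs)])
  perfusion_protocol(segs)
}

#' Analysis windows implied by a protocol
#'
#' Derives, from the segment timeline, the windows the feature-extraction
#' stage uses: the normalization baseline (final `baseline_s` seconds before
#' the first buffer change), the window following the first hexose removal,
#' the window following the first hexose substitution (glucose replaced by
#' another hexose), and the window following oligomycin onset.
#'
#' @param protocol a [perfusion_protocol()].
#' @param baseline_s length of the pre-stimulus baseline window (s).
#' @return list with elements `baseline`, and where applicable `glc_removal`,
#'   `substitution`, `oligo`, each a numeric `c(t0, t1)`.
#' @export
protocol_windows <- function(protocol, baseline_s = 60) {
  s <- protocol$segments
  first_change <- if (nrow(s) > 1) s$t_end[1] else protocol$total_duration
  w <- list(baseline = c(max(0, first_change - baseline_s), first_change))

  window_from <- function(t0) {
    # up to the next segment whose buffer differs from the one at t0
    i <- segment_index_at(protocol, t0)
    j <- i
    while (j < nrow(s) &&
           s$hexose[j + 1] == s$hexose[i] &&
           s$oligomycin[j + 1] == s$oligomycin[i] &&
           s$antimycin[j + 1] == s$antimycin[i]) j <- j + 1
    c(t0, s$t_end[j])
  }
  prev_hex <- c(NA, s$hexose[-nrow(s)])
  rem <- which(s$hexose == "none" & prev_hex != "none")
  if (length(rem)) w$glc_removal <- window_from(s$t_start[rem[1]])
  sub <- which(s$hexose %in% c("mannose", "dg2") & prev_hex == "glucose")
  if (length(sub)) w$substitution <- window_from(s$t_start[sub[1]])
  prev_ol <- c(FALSE, s$oligomycin[-nrow(s)])
  ol <- which(s$oligomycin & !prev_ol)
  if (length(ol)) w$oligo <- c(s$t_start[ol[1]], protocol$total_duration)
  w
}

#' Times at which hexose is removed (switch to sugar-free buffer)
#' @param protocol a [perfusion_protocol()].
#' @return numeric vector of removal onset times (s), possibly empty.
#' @export
removal_times <- function(protocol) {
  s <- protocol$segments
  prev_hex <- c(NA, s$hexose[-nrow(s)])
  s$t_start[which(s$hexose == "none" & prev_hex != "none")]
}

#' Read/write protocols as YAML
#'
#' @param protocol a [perfusion_protocol()].
#' @param path file path.
#' @return `read_protocol` returns a [perfusion_protocol()];
#'   `write_protocol` returns `path` invisibly.
#' @export
write_protocol <- function(protocol, path) {
  obj <- list(format_version = 1L,
              drug_conc = as.list(protocol$drug_conc),
              segments = lapply(seq_len(nrow(protocol$segments)), function(i)
                as.list(protocol$segments[i, ])))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  obj <- yaml::read_yaml(path)
  segs <- do.call(rbind, lapply(obj$segments, function(s)
    data.frame(t_start = s$t_start, t_end = s$t_end, hexose = s$hexose,
               hexose_conc = s$hexose_conc, oligomycin = s$oligomycin,
               antimycin = s$antimycin, stringsAsFactors = FALSE)))
  perfusion_protocol(segs, drug_conc = unlist(obj$drug_conc))
}
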