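#' Reversible hexokinase flux
#'
#' Mass-action net flux of the hexokinase reaction, coupled to the
#' mitochondrial adenine pool: positive flux phosphorylates hexose using
#' matrix-derived ATP; negative flux converts hexose-6-phosphate back to
#' hexose, returning ATP to the matrix. This reversibility is what produces
#' the transient mitochondrial ATP rise when the hexose substrate is removed.
#'
#' @param glc_c intracellular free hexose (mM).
#' @param h6p hexose-6-phosphate pool (mM).
#' @param atp_m,adp_m mitochondrial ATP and ADP (mM).
#' @param arch a [cell_archetype()] supplying `k_hk_f` and `k_hk_r`.
#' @return Net flux in mM/s; positive = phosphorylation.
#' @export
hk_flux <- function(glc_c, h6p, atp_m, adp_m, arch) {
  if (any(c(glc_c, h6p, atp_m, adp_m) < 0))
    stop("hk_flux: negative inputs")
  arch$k_hk_f * glc_c * atp_m - arch$k_hk_r * h6p * adp_m
}

# Right-hand side of the compartmental ATP model for fixed buffer conditions.
#
# State: glc_c, h6p_met (metabolizable, glucose-derived), h6p_non
# (mannose/2-DG-derived, not further metabolized), atp_c, atp_m, atp_er.
# ATP-producing fluxes are scaled by the free-ADP fraction of the target
# pool and the ANT term is a mass-action antiport, so adenine conservation
# (0 <= atp_x <= a_tot_x) holds structurally for every parameter set.
atp_rhs <- function(state, arch, hexose = "glucose", conc = 10,
                    oligomycin = FALSE, antimycin = FALSE,
                    resident_hexose = hexose, hk_atp_source = "mito") {
  s <- pmax(state, 0)
  glc_c <- s[["glc_c"]]; h6p_met <- s[["h6p_met"]]; h6p_non <- s[["h6p_non"]]
  atp_c <- min(s[["atp_c"]], arch$a_tot_c)
  atp_m <- min(s[["atp_m"]], arch$a_tot_m)
  atp_er <- s[["atp_er"]]
  adp_c <- arch$a_tot_c - atp_c
  adp_m <- arch$a_tot_m - atp_m

  hk_atp  <- if (hk_atp_source == "mito") atp_m else atp_c
  hk_adp  <- if (hk_atp_source == "mito") adp_m else adp_c
  v_hk_f <- arch$k_hk_f * glc_c * hk_atp
  v_hk_r_met <- arch$k_hk_r * h6p_met * hk_adp
  v_hk_r_non <- arch$k_hk_r * h6p_non * hk_adp
  v_hk_net <- v_hk_f - v_hk_r_met - v_hk_r_non

  E <- if (hexose == "none") 0 else conc
  v_in <- arch$v_glut * (E - glc_c)
  # 2-DG-6-phosphate inhibits downstream glycolysis while 2-DG is present
  v_glyc <- if (hexose == "dg2") 0 else arch$k_gly * h6p_met

  to_met <- resident_hexose == "glucose"
  s_oligo <- if (oligomycin) 0 else 1
  s_anti <- if (antimycin) 0 else 1
  ex <- arch$k_ant * (atp_c * adp_m / arch$a_tot_m -
                      atp_m * adp_c / arch$a_tot_c)

  d_glc <- v_in - v_hk_f + v_hk_r_met + v_hk_r_non
  d_h6p_met <- (if (to_met) v_hk_f else 0) - v_hk_r_met - v_glyc
  d_h6p_non <- (if (to_met) 0 else v_hk_f) - v_hk_r_non
  d_atp_c <- arch$y_atp * v_glyc * (adp_c / arch$a_tot_c) - ex -
    arch$k_cons_c * atp_c - arch$k_er_in * atp_c -
    (if (hk_atp_source == "cyto") v_hk_net else 0)
  d_atp_m <- ex - (if (hk_atp_source == "mito") v_hk_net else 0) +
    s_oligo * (arch$v_ox * s_anti * (adp_m / arch$a_tot_m) -
               arch$k_hyd * atp_m) -
    arch$k_cons_m * atp_m
  d_atp_er <- arch$k_er_in * atp_c - arch$k_er_cons * atp_er

  c(glc_c = d_glc, h6p_met = d_h6p_met, h6p_non = d_h6p_non,
    atp_c = d_atp_c, atp_m = d_atp_m, atp_er = d_atp_er)
}

default_init_state <- function(arch) {
  c(glc_c = 5, h6p_met = 1, h6p_non = 0,
    atp_c = arch$a_tot_c / 2, atp_m = arch$a_tot_m / 2, atp_er = 0.5)
}

#' Basal steady state of the compartmental model
#'
#' Integrates the model under fixed buffer conditions until the state stops
#' changing, giving the basal operating point of an archetype.
#'
#' @param arch a [cell_archetype()].
#' @param hexose,conc buffer hexose and concentration (mM).
#' @param oligomycin,antimycin drug flags.
#' @param t_max integration horizon (s).
#' @param hk_atp_source `"mito"` (default) or `"cyto"`: which pool the
#'   hexokinase draws on.
#' @return Named state vector at steady state.
#' @export
steady_state <- function(arch, hexose = "glucose", conc = 10,
                         oligomycin = FALSE, antimycin = FALSE,
                         t_max = 50000, hk_atp_source = "mito") {
  f <- function(t, y, parms)
    list(atp_rhs(y, arch, hexose, conc, oligomycin, antimycin,
                 resident_hexose = hexose, hk_atp_source = hk_atp_source))
  out <- deSolve::lsoda(default_init_state(arch), c(0, t_max), f, NULL,
                        rtol = 1e-10, atol = 1e-12)
  y <- out[nrow(out), -1]
  stats::setNames(as.numeric(y), colnames(out)[-1])
}

#' Simulate a single cell through a perfusion protocol
#'
#' Integrates the compartmental ATP model piecewise over the protocol's
#' buffer segments. The hexose-6-phosphate pool is tracked separately by the
#' hexose that produced it (glucose-derived, metabolizable, versus
#' mannose/2-DG-derived, not metabolizable), so a mannose-to-sugar-free
#' switch leaves a phosphorylated pool available to the reverse hexokinase
#' reaction. Before the protocol starts the cell is equilibrated under the
#' first segment's conditions, so the recording begins at the basal steady
#' state.
#'
#' @param arch a [cell_archetype()].
#' @param protocol a [perfusion_protocol()].
#' @param dt_out output grid spacing (s); default 1 s, mimicking imaging
#'   cadence.
#' @param rtol,atol solver tolerances.
#' @param equilibrate pre-equilibrate under the first segment (default TRUE).
#' @param init optional initial state (used when `equilibrate = FALSE`).
#' @param hk_atp_source `"mito"` or `"cyto"` (sensitivity analysis).
#' @return Object of class `sim_trace`: data.frame with columns `time`,
#'   `glc_c`, `h6p`, `h6p_met`, `h6p_non`, `atp_c`, `atp_m`, `atp_er`, with
#'   the protocol and archetype attached as attributes.
#' @export
simulate_cell <- function(arch, protocol, dt_out = 1, rtol = 1e-8,
                          atol = 1e-10, equilibrate = TRUE, init = NULL,
                          hk_atp_source = c("mito", "cyto")) {
  stopifnot(inherits(arch, "cell_archetype"),
            inherits(protocol, "perfusion_protocol"))
  hk_atp_source <- match.arg(hk_atp_source)
  segs <- protocol$segments

  if (is.null(init)) {
    init <- if (equilibrate)
      steady_state(arch, segs$hexose[1], segs$hexose_conc[1],
                   segs$oligomycin[1], segs$antimycin[1],
                   hk_atp_source = hk_atp_source)
    else default_init_state(arch)
  }

  state <- init
  resident <- if (segs$hexose[1] == "none") "glucose" else segs$hexose[1]
  rows <- vector("list", nrow(segs))
  for (i in seq_len(nrow(segs))) {
    if (segs$hexose[i] != "none") resident <- segs$hexose[i]
    f <- function(t, y, parms)
      list(atp_rhs(y, arch, segs$hexose[i], segs$hexose_conc[i],
                   segs$oligomycin[i], segs$antimycin[i],
                   resident_hexose = resident,
                   hk_atp_source = hk_atp_source))
    times <- seq(segs$t_start[i], segs$t_end[i], by = dt_out)
    if (times[length(times)] < segs$t_end[i]) times <- c(times, segs$t_end[i])
    sol <- deSolve::lsoda(state, times, f, NULL, rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0) stop("ODE solver failed in segment ", i)
    state <- stats::setNames(as.numeric(sol[nrow(sol), -1]),
                             colnames(sol)[-1])
    keep <- if (i < nrow(segs)) sol[-nrow(sol), , drop = FALSE] else sol
    rows[[i]] <- keep
  }
  m <- do.call(rbind, rows)
  df <- as.data.frame(m)
  names(df)[1] <- "time"
  # clip solver-tolerance-level excursions to the physical bounds
  for (v in c("glc_c", "h6p_met", "h6p_non", "atp_c", "atp_m", "atp_er"))
    df[[v]] <- pmax(df[[v]], 0)
  df$atp_c <- pmin(df$atp_c, arch$a_tot_c)
  df$atp_m <- pmin(df$atp_m, arch$a_tot_m)
  df$h6p <- df$h6p_met + df$h6p_non
  df <- df[c("time", "glc_c", "h6p", "h6p_met", "h6p_non",
             "atp_c", "atp_m", "atp_er")]
  structure(df, protocol = protocol, archetype = arch,
            class = c("sim_trace", "data.frame"))
}

#' Export a simulated trace as tidy CSV
#'
#' Long format with columns `time_s`, `variable`, `value_mM`, `cell_id`.
#'
#' @param sim a `sim_trace`.
#' @param path output file.
#' @param cell_id identifier written to the `cell_id` column.
#' @export
write_sim_trace <- function(sim, path, cell_id = attr(sim, "archetype")$label) {
  vars <- c("glc_c", "h6p", "atp_c", "atp_m", "atp_er")
  long <- do.call(rbind, lapply(vars, function(v)
    data.frame(time_s = sim$time, variable = v, value_mM = sim[[v]],
               cell_id = cell_id, stringsAsFactors = FALSE)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# atpfret sim_trace format_version=1", con)
  utils::write.csv(long, con, row.names = FALSE)
  invisible(path)
}
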