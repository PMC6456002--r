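#' Cell archetypes: rate-parameter sets of the compartmental ATP model
#'
#' An archetype is the full rate-parameter set of the bioenergetics model and
#' defines a metabolic setting. `"hela_like"` and `"mef_young_like"` are
#' glycolytic settings: low OXPHOS output, net reverse-mode ATP synthase
#' (matrix ATP hydrolysis sustains the membrane potential), strong
#' mitochondria-coupled hexokinase flux. `"beta_like"`, `"mef_old_like"` and
#' `"mfn2_ko_like"` are oxidative settings: OXPHOS dominates matrix ATP
#' supply and the synthase runs forward.
#'
#' All rate constants are calibrated, not measured: they were chosen once so
#' that the qualitative behaviours the model is meant to emulate hold
#' (basal compartment ordering, transient mitochondrial peak on hexose
#' removal, depletion ordering 2-DG < mannose < glucose removal, the
#' oligomycin dichotomy), and are documented as such.
#'
#' @param v_glut hexose transport rate (1/s), first-order equilibration of
#'   intracellular toward extracellular hexose.
#' @param k_hk_f,k_hk_r forward/reverse hexokinase mass-action rates
#'   (1/(mM*s)); HK draws on and returns to the mitochondrial ATP pool.
#' @param k_gly downstream glycolytic rate (1/s) acting on metabolizable
#'   hexose-6-phosphate.
#' @param y_atp cytosolic ATP yield per hexose-6-phosphate consumed.
#' @param v_ox OXPHOS ATP production capacity (mM/s).
#' @param k_hyd reverse-mode ATP-synthase hydrolysis rate (1/s).
#' @param k_ant ANT antiport exchange rate (1/s).
#' @param k_cons_c,k_cons_m compartment ATP consumption rates (1/s).
#' @param k_er_in,k_er_cons ER ATP import and consumption rates (1/s).
#' @param a_tot_c,a_tot_m total adenine pools (mM); ADP is implicit,
#'   `adp_x = a_tot_x - atp_x`.
#' @param label archetype name.
#' @return Object of class `cell_archetype` (a named list).
#' @export
cell_archetype <- function(v_glut, k_hk_f, k_hk_r, k_gly, y_atp, v_ox, k_hyd,
                           k_ant, k_cons_c, k_cons_m, k_er_in, k_er_cons,
                           a_tot_c, a_tot_m, label = "custom") {
  a <- list(v_glut = v_glut, k_hk_f = k_hk_f, k_hk_r = k_hk_r, k_gly = k_gly,
            y_atp = y_atp, v_ox = v_ox, k_hyd = k_hyd, k_ant = k_ant,
            k_cons_c = k_cons_c, k_cons_m = k_cons_m, k_er_in = k_er_in,
            k_er_cons = k_er_cons, a_tot_c = a_tot_c, a_tot_m = a_tot_m,
            label = label)
  num <- unlist(a[archetype_rate_names()])
  if (any(!is.finite(num)) || any(num < 0))
    stop("all archetype rates and pools must be finite and >= 0")
  if (a_tot_c <= 0 || a_tot_m <= 0) stop("adenine pools must be > 0")
  class(a) <- "cell_archetype"
  a
}

# parameter names subject to population (log-normal) variation
archetype_rate_names <- function() {
  c("v_glut", "k_hk_f", "k_hk_r", "k_gly", "y_atp", "v_ox", "k_hyd", "k_ant",
    "k_cons_c", "k_cons_m", "k_er_in", "k_er_cons")
}

#' @export
print.cell_archetype <- function(x, ...) {
  cat("<cell_archetype> ", x$label, "\n", sep = "")
  v <- unlist(x[setdiff(names(x), "label")])
  print(signif(v, 4))
  invisible(x)
}

#' @rdname cell_archetype
#' @param name one of `"hela_like"`, `"beta_like"`, `"mef_young_like"`,
#'   `"mef_old_like"`, `"mfn2_ko_like"`.
#' @export
archetype <- function(name) {
  name <- match.arg(name, c("hela_like", "beta_like", "mef_young_like",
                            "mef_old_like", "mfn2_ko_like"))
  base <- list(
    hela_like = list(
      v_glut = 0.30, k_hk_f = 0.00054, k_hk_r = 0.00050, k_gly = 0.0100,
      y_atp = 3, v_ox = 0.0006, k_hyd = 0.0020, k_ant = 0.0100,
      k_cons_c = 0.0006, k_cons_m = 0.0002, k_er_in = 0.0003,
      k_er_cons = 0.0012, a_tot_c = 5, a_tot_m = 5),
    beta_like = list(
      v_glut = 0.30, k_hk_f = 0.00020, k_hk_r = 0.00010, k_gly = 0.0100,
      y_atp = 3, v_ox = 0.0300, k_hyd = 0.0002, k_ant = 0.0030,
      k_cons_c = 0.0020, k_cons_m = 0.0030, k_er_in = 0.0003,
      k_er_cons = 0.0012, a_tot_c = 5, a_tot_m = 5),
    mef_young_like = list(
      v_glut = 0.30, k_hk_f = 0.00044, k_hk_r = 0.00040, k_gly = 0.0100,
      y_atp = 3, v_ox = 0.0008, k_hyd = 0.0018, k_ant = 0.0100,
      k_cons_c = 0.0006, k_cons_m = 0.0002, k_er_in = 0.0003,
      k_er_cons = 0.0012, a_tot_c = 5, a_tot_m = 5),
    mef_old_like = list(
      v_glut = 0.30, k_hk_f = 0.00016, k_hk_r = 0.00016, k_gly = 0.0100,
      y_atp = 3, v_ox = 0.0220, k_hyd = 0.0002, k_ant = 0.0030,
      k_cons_c = 0.0018, k_cons_m = 0.0024, k_er_in = 0.0003,
      k_er_cons = 0.0012, a_tot_c = 5, a_tot_m = 5),
    mfn2_ko_like = list(
      v_glut = 0.30, k_hk_f = 0.00018, k_hk_r = 0.00018, k_gly = 0.0100,
      y_atp = 3, v_ox = 0.0260, k_hyd = 0.0002, k_ant = 0.0030,
      k_cons_c = 0.0019, k_cons_m = 0.0027, k_er_in = 0.0003,
      k_er_cons = 0.0012, a_tot_c = 5, a_tot_m = 5))[[name]]
  do.call(cell_archetype, c(base, list(label = name)))
}

#' Scale hexokinase activity of an archetype
#'
#' Multiplies both the forward and reverse hexokinase rates by `alpha`,
#' emulating partial (siRNA-style) knockdown of mitochondria-located
#' hexokinases; `alpha = 0` abolishes HK flux entirely.
#'
#' @param arch a [cell_archetype()].
#' @param alpha scale factor in `[0, 1]` (values > 1 are allowed and mean
#'   overexpression).
#' @export
scale_hk <- function(arch, alpha) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0)
  arch$k_hk_f <- arch$k_hk_f * alpha
  arch$k_hk_r <- arch$k_hk_r * alpha
  arch$label <- sprintf("%s_hk%.2g", arch$label, alpha)
  arch
}

#' Sample a population of archetypes with cell-to-cell variability
#'
#' Each rate parameter is independently multiplied by a log-normal factor
#' with median 1 and coefficient of variation `cv`, modelling the strong
#' cell-to-cell variability of single-cell ATP responses. Adenine pool sizes
#' are held fixed. Deterministic for a fixed `seed`.
#'
#' @param arch base [cell_archetype()].
#' @param n number of cells (>= 1).
#' @param cv coefficient of variation of the log-normal factors (>= 0).
#' @param seed integer seed.
#' @return list of `n` `cell_archetype` objects.
#' @export
sample_population <- function(arch, n, cv = 0.3, seed = 1L) {
  stopifnot(inherits(arch, "cell_archetype"))
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  if (!is.numeric(cv) || cv < 0) stop("cv must be >= 0")
  n <- as.integer(n)
  rn <- archetype_rate_names()
  sdlog <- sqrt(log1p(cv^2))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    a <- arch
    if (cv > 0) {
      fac <- stats::rlnorm(length(rn), meanlog = 0, sdlog = sdlog)
      for (j in seq_along(rn)) a[[rn[j]]] <- a[[rn[j]]] * fac[j]
    }
    a$label <- sprintf("%s_%03d", arch$label, i)
    a
  })
}
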