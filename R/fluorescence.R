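#' Sensor and acquisition models
#'
#' `sensor_model()` describes a ratiometric FRET ATP biosensor by its
#' apparent affinity `kd` (mM), Hill coefficient, and the ideal ratio at zero
#' and saturating ATP (`r_min`, `r_max`). `default_sensor()` returns the
#' per-compartment defaults used throughout the package: the cytosolic
#' sensor is high-affinity relative to basal cytosolic ATP (so it reports
#' near saturation and compresses large ATP swings into moderate ratio
#' changes), the mitochondrial sensor sits mid-dynamic-range at basal matrix
#' ATP (maximal sensitivity), and the ER sensor is low-affinity. All
#' affinities are calibration choices of this package, not measured sensor
#' constants.
#'
#' @param kd apparent affinity (mM), > 0.
#' @param hill Hill coefficient, > 0.
#' @param r_min,r_max ratio at 0 and saturating ATP; `r_max > r_min > 0`.
#' @return An object of class `sensor_model`.
#' @export
sensor_model <- function(kd = 2, hill = 2, r_min = 0.5, r_max = 3) {
  if (kd <= 0 || hill <= 0) stop("kd and hill must be > 0")
  if (!(r_max > r_min && r_min > 0)) stop("need r_max > r_min > 0")
  structure(list(kd = kd, hill = hill, r_min = r_min, r_max = r_max),
            class = "sensor_model")
}

#' @rdname sensor_model
#' @param compartment `"cyto"`, `"mito"` or `"er"`.
#' @export
default_sensor <- function(compartment = c("cyto", "mito", "er")) {
  compartment <- match.arg(compartment)
  switch(compartment,
         cyto = sensor_model(kd = 0.15, hill = 2),
         mito = sensor_model(kd = 2.0, hill = 2),
         er   = sensor_model(kd = 3.0, hill = 2))
}

#' @rdname sensor_model
#' @param gain_cfp,gain_yfp channel gains (counts per expression unit).
#' @param bg_cfp,bg_yfp additive background (counts).
#' @param bleach_rate_donor,bleach_rate_acceptor photobleaching rates (1/s).
#' @param noise_sd additive noise standard deviation (counts).
#' @param dt frame interval (s).
#' @param kappa donor quench efficiency at full occupancy (bleed constant).
#' @param gamma acceptor direct-excitation fraction (bleed constant).
#' @param noise `"gaussian"` (default, keeps closed-form standard-error
#'   checks exact) or `"poisson"`.
#' @export
acquisition_model <- function(gain_cfp = 600, gain_yfp = 600,
                              bg_cfp = 50, bg_yfp = 50,
                              bleach_rate_donor = 0, bleach_rate_acceptor = 0,
                              noise_sd = 0, dt = 1,
                              kappa = 0.7, gamma = 0.2,
                              noise = c("gaussian", "poisson")) {
  noise <- match.arg(noise)
  v <- c(gain_cfp, gain_yfp, bg_cfp, bg_yfp, bleach_rate_donor,
         bleach_rate_acceptor, noise_sd, dt, kappa, gamma)
  if (any(v < 0)) stop("acquisition parameters must be non-negative")
  if (dt <= 0) stop("dt must be > 0")
  structure(list(gain_cfp = gain_cfp, gain_yfp = gain_yfp, bg_cfp = bg_cfp,
                 bg_yfp = bg_yfp, bleach_rate_donor = bleach_rate_donor,
                 bleach_rate_acceptor = bleach_rate_acceptor,
                 noise_sd = noise_sd, dt = dt, kappa = kappa, gamma = gamma,
                 noise = noise),
            class = "acquisition_model")
}

#' Sensor occupancy and ideal ratio
#'
#' `occupancy()` is the Hill binding curve
#' `f = atp^hill / (kd^hill + atp^hill)`; `ratio_from_occupancy()` maps an
#' occupancy to the sensor's ideal ratio `r_min + f * (r_max - r_min)`;
#' `occupancy_to_atp()` inverts the binding curve.
#'
#' @param atp ATP concentration (mM), >= 0.
#' @param sensor a [sensor_model()].
#' @return Occupancy fraction in `[0, 1]`.
#' @export
occupancy <- function(atp, sensor) {
  if (any(atp < 0)) stop("atp must be >= 0")
  a <- atp^sensor$hill
  a / (sensor$kd^sensor$hill + a)
}

#' @rdname occupancy
#' @param f occupancy fraction in `[0, 1]`.
#' @export
ratio_from_occupancy <- function(f, sensor) {
  if (any(f < 0 | f > 1)) stop("occupancy must lie in [0, 1]")
  sensor$r_min + f * (sensor$r_max - sensor$r_min)
}

#' @rdname occupancy
#' @export
occupancy_to_atp <- function(f, sensor) {
  if (any(f < 0 | f >= 1)) stop("occupancy must lie in [0, 1)")
  sensor$kd * (f / (1 - f))^(1 / sensor$hill)
}

# mean (noiseless, unbleached) channel intensities for occupancy f
channel_means <- function(f, acq, expression_level = 1) {
  list(cfp = acq$gain_cfp * expression_level * (1 - acq$kappa * f),
       yfp = acq$gain_yfp * expression_level * (acq$gamma + f))
}

#' Render a simulated ATP trajectory into a dual-channel trace
#'
#' Forward model of acquisition: per frame, sensor occupancy drives the two
#' emission channels `cfp = g_c * E * (1 - kappa * f) * exp(-k_d * t) + bg_c`
#' and `yfp = g_y * E * (gamma + f) * exp(-k_a * t) + bg_y`, with additive
#' noise. The true background values are stored with the trace. The
#' resulting YFP/CFP ratio (after background subtraction) is a strictly
#' increasing transform of occupancy and independent of `expression_level`.
#'
#' @param sim a `sim_trace` from [simulate_cell()].
#' @param compartment `"cyto"`, `"mito"` or `"er"`.
#' @param sensor a [sensor_model()]; defaults to the compartment's
#'   [default_sensor()].
#' @param acq an [acquisition_model()].
#' @param expression_level sensor expression (arbitrary units).
#' @param seed integer seed for the noise (NULL = use current RNG state).
#' @param cell_id identifier attached to the trace.
#' @return A `dual_channel_trace` (see [dual_channel_trace()]).
#' @export
render_trace <- function(sim, compartment = c("mito", "cyto", "er"),
                         sensor = NULL, acq = acquisition_model(),
                         expression_level = 1, seed = NULL,
                         cell_id = "cell_1") {
  compartment <- match.arg(compartment)
  if (is.null(sensor)) sensor <- default_sensor(compartment)
  atp <- switch(compartment, cyto = sim$atp_c, mito = sim$atp_m,
                er = sim$atp_er)
  t <- sim$time
  f <- occupancy(atp, sensor)
  mu <- channel_means(f, acq, expression_level)
  cfp <- mu$cfp * exp(-acq$bleach_rate_donor * t) + acq$bg_cfp
  yfp <- mu$yfp * exp(-acq$bleach_rate_acceptor * t) + acq$bg_yfp
  if (!is.null(seed)) set.seed(seed)
  if (acq$noise_sd > 0 || acq$noise == "poisson") {
    if (acq$noise == "gaussian") {
      cfp <- cfp + stats::rnorm(length(t), 0, acq$noise_sd)
      yfp <- yfp + stats::rnorm(length(t), 0, acq$noise_sd)
    } else {
      cfp <- stats::rpois(length(t), cfp)
      yfp <- stats::rpois(length(t), yfp)
    }
  }
  dual_channel_trace(time = t, cfp = cfp, yfp = yfp,
                     bg_cfp_est = acq$bg_cfp, bg_yfp_est = acq$bg_yfp,
                     cell_id = cell_id, compartment = compartment,
                     sensor = sensor, acq = acq)
}

#' Invert a background-subtracted YFP/CFP ratio to ATP
#'
#' Closed-form inversion of the channel model (zero bleach): occupancy
#' `f = (R * g_c - g_y * gamma) / (g_y + R * g_c * kappa)`, then the Hill
#' curve inverse. Used for round-trip validation of the processing chain.
#'
#' @param ratio background-subtracted YFP/CFP ratio.
#' @param sensor a [sensor_model()].
#' @param acq the [acquisition_model()] used for rendering.
#' @return ATP (mM).
#' @export
invert_ratio <- function(ratio, sensor, acq) {
  f <- (ratio * acq$gain_cfp - acq$gain_yfp * acq$gamma) /
    (acq$gain_yfp + ratio * acq$gain_cfp * acq$kappa)
  f <- pmin(pmax(f, 0), 1 - 1e-12)
  occupancy_to_atp(f, sensor)
}

#' Ideal (noise-free, background-free) ratio for an ATP level
#'
#' The YFP/CFP ratio the channel model produces at a given ATP
#' concentration, with no bleach, noise, or background — the ground truth
#' the processing chain should recover.
#'
#' @param atp ATP (mM).
#' @inheritParams invert_ratio
#' @export
true_ratio <- function(atp, sensor, acq = acquisition_model()) {
  f <- occupancy(atp, sensor)
  mu <- channel_means(f, acq)
  mu$yfp / mu$cfp
}
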