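test_that("hexokinase flux follows reversible mass action", {
  a <- archetype("hela_like")
  # no substrate in either direction
  expect_identical(hk_flux(0, 0, 1.5, 3.5, a), 0)
  # pure reverse: ATP produced into mitochondria
  a0 <- a; a0$k_hk_f <- 0
  expect_lt(hk_flux(5, 2, 1.5, 3.5, a0), 0)
  expect_error(hk_flux(-1, 0, 1, 1, a), "negative")

  # detailed-balance point found numerically as oracle: flux there is 0
  glc <- 4; atp_m <- 1.2; adp_m <- 3.8
  h6p_star <- stats::uniroot(
    function(h) a$k_hk_f * glc * atp_m - a$k_hk_r * h * adp_m,
    c(0, 1e4))$root
  expect_equal(hk_flux(glc, h6p_star, atp_m, adp_m, a), 0,
               tolerance = 1e-10)
})

test_that("null dynamics leave the state constant", {
  a <- cell_archetype(v_glut = 0, k_hk_f = 0, k_hk_r = 0, k_gly = 0,
                      y_atp = 0, v_ox = 0, k_hyd = 0, k_ant = 0,
                      k_cons_c = 0, k_cons_m = 0, k_er_in = 0,
                      k_er_cons = 0, a_tot_c = 5, a_tot_m = 5)
  sim <- simulate_cell(a, make_protocol("glucose_removal"),
                       dt_out = 10, equilibrate = FALSE,
                       init = c(glc_c = 2, h6p_met = 1, h6p_non = 0.5,
                                atp_c = 3, atp_m = 1, atp_er = 0.4))
  for (v in c("h6p_met", "h6p_non", "atp_c", "atp_m", "atp_er"))
    expect_equal(sim[[v]], rep(sim[[v]][1], nrow(sim)), tolerance = 1e-8)
  # glc_c still washes in/out through the transporter only if v_glut > 0
  expect_equal(sim$glc_c, rep(2, nrow(sim)), tolerance = 1e-8)
})

test_that("terminal state under constant glucose matches the ODE fixed point", {
  skip_if_not_installed("pracma")
  a <- archetype("hela_like")
  ss <- steady_state(a)
  # independent oracle: root-find the right-hand side
  rhs <- function(x) {
    x <- stats::setNames(as.numeric(x),
                         c("glc_c", "h6p_met", "h6p_non",
                           "atp_c", "atp_m", "atp_er"))
    unname(atpfret:::atp_rhs(x, a, hexose = "glucose", conc = 10))
  }
  root <- pracma::fsolve(rhs, unname(ss) + 0.01)$x
  expect_equal(unname(ss), root, tolerance = 1e-5)
  expect_lt(max(abs(rhs(unname(ss)))), 1e-8)
})

test_that("glucose removal produces a transient matrix-ATP peak then depletion", {
  sim <- fixture_sim("glucose_removal")
  basal <- mean(sim$atp_m[sim$time >= 240 & sim$time < 300])
  post <- sim[sim$time >= 300, ]
  expect_gt(max(post$atp_m), basal * 1.1)          # transient rise
  expect_lt(post$atp_m[nrow(post)], basal * 0.7)   # prominent depletion
  # the peak precedes the depletion minimum
  expect_lt(post$time[which.max(post$atp_m)],
            post$time[which.min(post$atp_m)])
})

test_that("adenine pools are conserved for sampled archetypes and protocols", {
  pop <- c(sample_population(archetype("hela_like"), 3, cv = 0.4, seed = 11),
           sample_population(archetype("beta_like"), 3, cv = 0.4, seed = 12))
  for (arch in pop) {
    for (proto in c("glc_removal_then_oligo", "dg2_substitution")) {
      sim <- simulate_cell(arch, make_protocol(proto), dt_out = 5)
      expect_true(all(sim$atp_c >= 0 & sim$atp_c <= arch$a_tot_c))
      expect_true(all(sim$atp_m >= 0 & sim$atp_m <= arch$a_tot_m))
      expect_true(all(sim$atp_er >= 0 & sim$glc_c >= 0 & sim$h6p >= 0))
    }
  }
})

test_that("the mitochondrial peak is monotone in hexokinase activity", {
  a <- archetype("hela_like")
  amps <- vapply(c(1, 0.6, 0.3, 0), function(al) {
    sim <- simulate_cell(scale_hk(a, al), make_protocol("glucose_removal"),
                         dt_out = 2)
    basal <- mean(sim$atp_m[sim$time >= 240 & sim$time < 300])
    max(sim$atp_m[sim$time >= 300]) - basal
  }, numeric(1))
  expect_true(all(diff(amps) < 1e-9))
  expect_equal(amps[4], 0, tolerance = 1e-6)
})

test_that("2-DG depletes matrix ATP deeper than mannose, mannose deeper than removal", {
  a <- archetype("hela_like")
  mins <- vapply(
    c("dg2_substitution", "mannose_switch", "glucose_removal"),
    function(p) {
      sim <- simulate_cell(a, make_protocol(p), dt_out = 2)
      min(sim$atp_m[sim$time >= 300 & sim$time <= 900])
    }, numeric(1))
  expect_lt(mins[["dg2_substitution"]], mins[["mannose_switch"]])
  expect_lt(mins[["mannose_switch"]], mins[["glucose_removal"]])
})

test_that("oligomycin raises matrix ATP in the glycolytic archetype and lowers it in the oxidative one", {
  for (nm in c("hela_like", "beta_like")) {
    a <- archetype(nm)
    sim <- simulate_cell(a, make_protocol("oligo_then_glc_removal",
                                          list(oligo_s = 1200)),
                         dt_out = 2)
    basal <- mean(sim$atp_m[sim$time >= 240 & sim$time < 300])
    oligo_end <- sim$atp_m[sim$time == 900]  # end of the oligo-only phase
    if (nm == "hela_like") expect_gt(oligo_end, basal * 1.2)
    else expect_lt(oligo_end, basal * 0.8)
  }
})

test_that("successive depletions yield non-increasing peak amplitudes", {
  a <- archetype("hela_like")
  p <- make_protocol("repeated_depletion")
  sim <- simulate_cell(a, p, dt_out = 2)
  segs <- p$segments
  amps <- vapply(removal_times(p), function(t0) {
    j <- which(segs$t_start == t0)
    basal <- mean(sim$atp_m[sim$time >= t0 - 30 & sim$time < t0])
    max(sim$atp_m[sim$time >= t0 & sim$time <= segs$t_end[j]]) - basal
  }, numeric(1))
  expect_true(all(diff(amps) <= 1e-9))
  expect_lt(amps[3], amps[1])
})

test_that("population sampling is seeded, degenerate at cv = 0, and has log-normal moments", {
  a <- archetype("hela_like")
  expect_error(sample_population(a, 3, cv = -0.1), "cv")

  p0 <- sample_population(a, 4, cv = 0, seed = 5)
  for (cell in p0)
    expect_equal(cell$k_hk_f, a$k_hk_f)

  p1 <- sample_population(a, 5, cv = 0.3, seed = 9)
  p2 <- sample_population(a, 5, cv = 0.3, seed = 9)
  expect_equal(lapply(p1, function(x) x[1:14]),
               lapply(p2, function(x) x[1:14]))

  # mean of each parameter within 3 standard errors of the log-normal mean
  cv <- 0.3; n <- 1000
  pop <- sample_population(a, n, cv = cv, seed = 42)
  sdlog <- sqrt(log1p(cv^2))
  for (par in c("k_hk_f", "v_ox", "k_ant")) {
    vals <- vapply(pop, `[[`, numeric(1), par)
    mu <- a[[par]] * exp(sdlog^2 / 2)       # log-normal mean, median 1 factor
    se <- stats::sd(vals) / sqrt(n)
    expect_lt(abs(mean(vals) - mu), 3 * se)
  }
})

test_that("simulated traces export to tidy CSV", {
  sim <- fixture_sim("glucose_removal")
  path <- withr::local_tempfile(fileext = ".csv")
  write_sim_trace(sim, path)
  df <- utils::read.csv(path, comment.char = "#")
  expect_named(df, c("time_s", "variable", "value_mM", "cell_id"))
  expect_setequal(unique(df$variable),
                  c("glc_c", "h6p", "atp_c", "atp_m", "atp_er"))
  back <- df$value_mM[df$variable == "atp_m"]
  expect_equal(back, sim$atp_m)
})
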