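test_that("basal level is the mean over the pre-stimulus window", {
  rt <- ratio_trace_from(0:9, rep(2, 10))
  expect_equal(basal_level(rt, c(0, 9)), 2)
  rt2 <- ratio_trace_from(0:2, c(1, 2, 3))
  expect_equal(basal_level(rt2, c(0, 2)), 2)
  expect_error(basal_level(rt2, c(100, 110)), ">= 3")
})

test_that("peak amplitude measures the bump height, floored at zero", {
  bt <- bump_trace(height = 0.3)
  basal <- basal_level(bt, c(0, 99))
  expect_equal(peak_amplitude(bt, c(100, 250), basal), 0.3,
               tolerance = 1e-9)
  # monotone-declining trace: floor at 0
  dec <- ratio_trace_from(0:100, seq(1, 0.5, length.out = 101))
  expect_equal(peak_amplitude(dec, c(10, 100), 1), 0)
  # onset limits the search window
  late_bump <- bump_trace(height = 0.3, t_on = 180, t_peak = 220, t_off = 260)
  expect_equal(peak_amplitude(late_bump, c(100, 299), 1, onset = 150), 0)
})

test_that("onset rule fires at the documented threshold and persistence", {
  # flat normalized trace: no onset
  flat <- ratio_trace_from(0:199, rep(1, 200), normalized = TRUE)
  expect_true(is.na(onset_time(flat, 50)))

  # 1 until t=100 then linear decline of slope -0.01/s: first frame below
  # 0.99 at 1 s cadence is t = 102 (ratio at 101 is exactly 0.99, not below)
  t <- 0:300
  r <- ifelse(t <= 100, 1, 1 - 0.01 * (t - 100))
  rt <- ratio_trace_from(t, pmax(r, 0.01), normalized = TRUE)
  expect_equal(onset_time(rt, 100, noise_sd_est = 0), 102)

  # brute-force oracle over randomized traces
  set.seed(7)
  for (i in 1:25) {
    n <- 120
    rr <- 1 + cumsum(stats::rnorm(n, -0.002, 0.02))
    vv <- stats::runif(n) > 0.05
    rt <- ratio_trace_from(0:(n - 1), rr, valid = vv, normalized = TRUE)
    nse <- stats::runif(1, 0, 0.02)
    got <- onset_time(rt, 20, noise_sd_est = nse)
    # literal rule: first valid time >= stimulus with 3 consecutive valid
    # frames below threshold
    thr <- 1 - max(3 * nse, 0.01)
    idx <- which(rt$time >= 20 & vv)
    expected <- NA_real_
    for (j in seq_along(idx)) {
      if (j + 2 <= length(idx) &&
          all(rr[idx[j:(j + 2)]] < thr)) { expected <- idx[j] - 1; break }
    }
    expect_equal(got, expected)
  }
})

test_that("depletion minimum ignores invalid frames", {
  rt <- ratio_trace_from(0:2, c(1, 0.6, 0.8))
  expect_equal(depletion_minimum(rt, c(0, 2)), 0.6)
  rt2 <- ratio_trace_from(0:2, c(1, 0.6, 0.8),
                          valid = c(TRUE, FALSE, TRUE))
  expect_equal(depletion_minimum(rt2, c(0, 2)), 0.8)
  expect_equal(depletion_minimum(ratio_trace_from(0:5, rep(1.3, 6)),
                                 c(0, 5)), 1.3)
  rt3 <- ratio_trace_from(0:2, c(1, 1, 1), valid = rep(FALSE, 3))
  expect_error(depletion_minimum(rt3, c(0, 2)), "no valid frames")
})

test_that("max change returns the signed largest-magnitude excursion", {
  # drop from 1 to 0.7
  rt <- ratio_trace_from(0:10, c(1, 1, seq(1, 0.7, length.out = 9)))
  expect_equal(max_change(rt, c(2, 10), c(0, 1)), -0.3)
  # up 0.2 then down to 0.9: the up-excursion wins
  r2 <- c(1, 1, 1.1, 1.2, 1.05, 0.95, 0.9)
  rt2 <- ratio_trace_from(0:6, r2)
  expect_equal(max_change(rt2, c(2, 6), c(0, 1)), 0.2)
  expect_error(max_change(rt2, c(2, 6), c(0, 3)), "precede")

  # brute-force oracle on randomized traces
  set.seed(13)
  for (i in 1:25) {
    n <- 60
    rr <- 1 + cumsum(stats::rnorm(n, 0, 0.05))
    vv <- stats::runif(n) > 0.1
    vv[1:10] <- TRUE
    rt <- ratio_trace_from(0:(n - 1), rr, valid = vv)
    got <- max_change(rt, c(10, n - 1), c(0, 9))
    b <- mean(rr[1:10])
    cand <- rr[11:n][vv[11:n]]
    expected <- cand[which.max(abs(cand - b))] - b
    expect_equal(got, expected)
  }
})

test_that("peak width is the interpolated full width at half maximum", {
  # symmetric triangular bump, base 100 s: FWHM = 50 s
  bt <- bump_trace(height = 0.4, t_on = 100, t_peak = 150, t_off = 200)
  expect_equal(peak_width(bt, c(90, 260), basal = 1), 50, tolerance = 1e-9)
  # quarter-maximum width of the same triangle is 75 s
  expect_equal(peak_width(bt, c(90, 260), basal = 1, frac = 0.25), 75,
               tolerance = 1e-9)
  # no bump: undefined
  flat <- ratio_trace_from(0:99, rep(1, 100))
  expect_true(is.na(peak_width(flat, c(0, 99), basal = 1)))
})

test_that("oligomycin prolongs the mannose-withdrawal peak", {
  widths <- vapply(c("mannose_switch", "mannose_switch_oligo"), function(p) {
    pr <- make_protocol(p)
    sim <- simulate_cell(archetype("hela_like"), pr, dt_out = 2)
    rt <- process_trace(render_trace(sim, "mito", acq = noiseless_acq()),
                        baseline_window = c(240, 300))
    t_wd <- removal_times(pr)[1]
    basal <- mean(rt$ratio[rt$time >= t_wd - 60 & rt$time < t_wd])
    peak_width(rt, c(t_wd, pr$total_duration), basal = basal)
  }, numeric(1))
  expect_gte(widths[["mannose_switch_oligo"]], widths[["mannose_switch"]])
})

test_that("features from a noiseless fixture match the sensor-transformed ground truth", {
  pr <- make_protocol("glucose_removal")
  sim <- fixture_sim("glucose_removal")
  acq <- noiseless_acq()
  rt <- process_trace(render_trace(sim, "mito", acq = acq),
                      baseline_window = c(240, 300))
  fe <- extract_features(rt, pr)

  # ground truth computed directly from the ATP trajectory
  r_true <- true_ratio(sim$atp_m, default_sensor("mito"), acq)
  b_true <- mean(r_true[sim$time >= 240 & sim$time < 300])
  norm_true <- r_true / b_true
  post <- sim$time >= 300
  expect_equal(fe$basal, 1, tolerance = 1e-9)
  expect_equal(fe$min_level, min(norm_true[post]), tolerance = 1e-6)
  d <- norm_true[post][which.max(abs(norm_true[post] - 1))] - 1
  expect_equal(fe$delta_glc, d, tolerance = 1e-6)
  expect_gt(fe$peak_amp, 0)
  expect_true(fe$qc_pass)
})

test_that("reducing generator HK rates monotonically reduces the extracted peak", {
  pr <- make_protocol("glucose_removal")
  amps <- vapply(c(1, 0.5, 0.2), function(al) {
    sim <- simulate_cell(scale_hk(archetype("hela_like"), al), pr,
                         dt_out = 2)
    rt <- process_trace(render_trace(sim, "mito", acq = noiseless_acq()),
                        baseline_window = c(240, 300))
    extract_features(rt, pr)$peak_amp
  }, numeric(1))
  expect_true(all(diff(amps) < 0))
})

test_that("cells with too many invalid frames fail QC", {
  pr <- make_protocol("glucose_removal", list(removal_s = 120))
  sim <- simulate_cell(archetype("hela_like"), pr, dt_out = 2)
  tr <- render_trace(sim, "mito", acq = noiseless_acq())
  tr$cfp[tr$time >= 320 & tr$time <= 400] <- 0   # saturated/lost frames
  rt <- process_trace(tr, baseline_window = c(240, 300))
  fe <- extract_features(rt, pr)
  expect_false(fe$qc_pass)
  expect_match(fe$qc_flags, "invalid_frames")
})
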