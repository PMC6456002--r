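test_that("background subtraction is per-channel arithmetic with invalid flagging", {
  tr <- dual_channel_trace(time = 0:1, cfp = c(100, 100), yfp = c(200, 200))
  out <- subtract_background(tr, bg_cfp = 40, bg_yfp = 0)
  expect_equal(out$cfp, c(60, 60))
  expect_equal(out$yfp, c(200, 200))
  expect_true(all(out$valid))

  id <- subtract_background(tr, 0, 0)
  expect_equal(id$cfp, tr$cfp)

  # over-subtraction flags frames invalid, no exception
  ov <- subtract_background(tr, bg_cfp = 150, bg_yfp = 0)
  expect_false(any(ov$valid))

  # no stored estimate and none given
  expect_error(subtract_background(tr), "no background")
})

test_that("ratio computation enforces processing order and invariances", {
  tr <- dual_channel_trace(time = 0:1, cfp = c(2, 4), yfp = c(3, 6))
  expect_error(compute_ratio(tr), "background")
  rt <- compute_ratio(subtract_background(tr, 0, 0))
  expect_equal(rt$ratio, c(1.5, 1.5))

  # yfp == cfp gives ratio 1; common scaling leaves the ratio unchanged
  tr1 <- dual_channel_trace(time = 0:2, cfp = c(5, 6, 7), yfp = c(5, 6, 7))
  expect_equal(compute_ratio(subtract_background(tr1, 0, 0))$ratio,
               rep(1, 3))
  c_ <- 3.7
  tr2 <- dual_channel_trace(time = 0:2, cfp = c_ * c(5, 6, 7),
                            yfp = c_ * c(5, 6, 7))
  expect_equal(compute_ratio(subtract_background(tr2, 0, 0))$ratio,
               compute_ratio(subtract_background(tr1, 0, 0))$ratio)

  # invalid frames propagate as NA
  tr3 <- dual_channel_trace(time = 0:2, cfp = c(5, 0.1, 7),
                            yfp = c(5, 6, 7))
  rt3 <- compute_ratio(subtract_background(tr3, 0.5, 0))
  expect_true(is.na(rt3$ratio[2]))
})

test_that("bleach correction recovers a known decay and flattens the trace", {
  t <- 0:600
  rt <- ratio_trace_from(t, 2 * exp(-0.001 * t))
  out <- correct_bleach(rt, list(c(0, 600)))
  fit <- attr(out, "bleach_fit")
  expect_true(fit$corrected)
  expect_lt(abs(fit$k - 0.001) / 0.001, 0.05)
  expect_true(all(abs(out$ratio - 2) / 2 < 0.01))
})

test_that("a flat trace is returned unchanged (decay below floor)", {
  t <- 0:100
  rt <- ratio_trace_from(t, rep(1.8, length(t)))
  out <- correct_bleach(rt, list(c(0, 100)))
  expect_false(attr(out, "bleach_fit")$corrected)
  expect_equal(out$ratio, rt$ratio)
})

test_that("correction from a pre-stimulus window preserves a step response", {
  t <- 0:500
  k <- 0.0008
  step <- ifelse(t >= 250, 1.5, 1)          # true biology: step up by 0.5
  rt <- ratio_trace_from(t, step * exp(-k * t))
  out <- correct_bleach(rt, list(c(0, 249)))  # quiescent = pre-stimulus only
  amp <- mean(out$ratio[t >= 400]) - mean(out$ratio[t < 200])
  expect_lt(abs(amp - 0.5) / 0.5, 0.02)
})

test_that("bleach correction demands enough quiescent frames", {
  t <- 0:100
  rt <- ratio_trace_from(t, exp(-0.001 * t))
  expect_error(correct_bleach(rt, list(c(0, 5))), ">= 10")
})

test_that("per-channel bleach correction flattens unequal channel decays", {
  t <- 0:400
  tr <- dual_channel_trace(time = t, cfp = 300 * exp(-4e-4 * t),
                          yfp = 500 * exp(-9e-4 * t))
  tr <- subtract_background(tr, 0, 0)
  out <- correct_bleach_channels(tr, list(c(0, 400)))
  expect_true(all(abs(out$cfp - 300) / 300 < 0.01))
  expect_true(all(abs(out$yfp - 500) / 500 < 0.01))
})

test_that("normalization sets the baseline mean to 1 and is idempotent", {
  rt <- ratio_trace_from(0:3, c(2, 2, 2, 4))
  out <- normalize_trace(rt, c(0, 2))
  expect_equal(out$ratio, c(1, 1, 1, 2))
  expect_true(attr(out, "normalized"))
  expect_equal(attr(out, "baseline_mean"), 2)
  again <- normalize_trace(out, c(0, 2))
  expect_equal(again$ratio, out$ratio)
  expect_error(normalize_trace(rt, c(10, 20)), ">= 3")
})

test_that("provenance records the enforced processing order", {
  sim <- fixture_sim("glucose_removal")
  tr <- render_trace(sim, "mito", acq = noiseless_acq())
  rt <- process_trace(tr, baseline_window = c(240, 300))
  expect_identical(attr(rt, "provenance"),
                   c("background_subtracted", "ratio_computed", "normalized"))
  # out-of-order: bleach correction after normalization fails
  expect_error(correct_bleach(rt, list(c(0, 300))), "before normalization")
})

test_that("expression scaling leaves the final normalized trace unchanged", {
  sim <- fixture_sim("glucose_removal")
  r1 <- process_trace(render_trace(sim, "mito", acq = noiseless_acq()),
                      baseline_window = c(240, 300))
  r2 <- process_trace(render_trace(sim, "mito", acq = noiseless_acq(),
                                   expression_level = 5),
                      baseline_window = c(240, 300))
  expect_equal(r2$ratio, r1$ratio, tolerance = 1e-12)
})

test_that("ROI segmentation recovers well-separated cells", {
  sims <- lapply(sample_population(archetype("hela_like"), 5, cv = 0.2,
                                   seed = 8),
                 simulate_cell,
                 protocol = make_protocol("glucose_removal",
                                          list(baseline_s = 60,
                                               removal_s = 60)),
                 dt_out = 30)
  st <- render_image_stack(sims, acq = acquisition_model(noise_sd = 1),
                           height = 96, width = 96, seed = 21)
  mask <- segment_rois(st)
  labs <- setdiff(unique(as.vector(mask)), 0)
  expect_length(labs, 5)
  # each found ROI overlaps exactly one truth cell with IoU >= 0.7
  for (l in labs) {
    found <- mask == l
    truth_label <- as.integer(names(which.max(
      table(st$truth_masks[found & st$truth_masks > 0]))))
    truth <- st$truth_masks == truth_label
    iou <- sum(found & truth) / sum(found | truth)
    expect_gte(iou, 0.7)
  }
  # determinism up to renumbering
  mask2 <- segment_rois(st)
  expect_identical(mask, mask2)
  # blank stack errors
  blank <- array(5, dim = c(2, 16, 16, 2))
  expect_error(segment_rois(blank), "no foreground")
})

test_that("ROI trace extraction equals the brute-force pixel average", {
  set.seed(99)
  frames <- array(stats::runif(4 * 12 * 12 * 2, 10, 100),
                  dim = c(4, 12, 12, 2))
  mask <- matrix(0L, 12, 12)
  mask[2:5, 2:5] <- 1L
  mask[8:11, 7:10] <- 2L
  traces <- extract_roi_traces(frames, mask, time = 1:4)
  for (l in 1:2) {
    sel <- mask == l
    for (k in 1:4) {
      expect_identical(traces[[l]]$cfp[k], mean(frames[k, , , 1][sel]))
      expect_identical(traces[[l]]$yfp[k], mean(frames[k, , , 2][sel]))
    }
  }
  # background estimate is the per-frame median over label-0 pixels
  expect_identical(traces[[1]]$bg_cfp_est[3],
                   stats::median(frames[3, , , 1][mask == 0]))

  # uniform ROI extracts a constant trace
  u <- array(7, dim = c(3, 6, 6, 2))
  m <- matrix(0L, 6, 6); m[2:4, 2:4] <- 1L
  tu <- extract_roi_traces(u, m, time = 1:3)
  expect_equal(tu[[1]]$cfp, rep(7, 3))
})

test_that("the full image round trip reproduces the rendered ratio", {
  sims <- lapply(sample_population(archetype("hela_like"), 2, cv = 0.2,
                                   seed = 31),
                 simulate_cell,
                 protocol = make_protocol("glucose_removal",
                                          list(baseline_s = 120,
                                               removal_s = 300)),
                 dt_out = 10)
  st <- render_image_stack(sims, acq = noiseless_acq(), seed = 5)
  traces <- extract_roi_traces(st)
  for (i in seq_along(traces)) {
    rt <- compute_ratio(subtract_background(traces[[i]], 0, 0))
    expect_lt(max(abs(rt$ratio - st$truth_traces[[i]]$ratio_true)), 1e-9)
  }
})
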