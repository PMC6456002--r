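#' Render a population of traces into a synthetic dual-channel image stack
#'
#' Draws each cell as a uniform-intensity ellipse at a random non-overlapping
#' position, fills frames with the cell's noiseless channel means from the
#' forward model, adds per-pixel Gaussian noise and additive background, and
#' records the ground-truth label mask and ATP trajectories. The stack is a
#' fixture for ROI-extraction tests, not an optics simulation.
#'
#' @param sims list of `sim_trace` objects (one per cell).
#' @param compartment compartment rendered (all cells the same).
#' @param sensor a [sensor_model()]; default per-compartment.
#' @param acq an [acquisition_model()]; `noise_sd` is per pixel.
#' @param height,width image size (pixels).
#' @param radius_range semi-axis range (pixels) of cell ellipses.
#' @param expression_levels per-cell expression (recycled).
#' @param seed integer seed (placement and noise).
#' @param max_tries placement retries before failing.
#' @return Object of class `synthetic_stack`: list with `frames`
#'   (T x H x W x 2 array, channels CFP then YFP), `truth_masks` (H x W
#'   integer label image, background 0), `truth_traces` (list of data.frames
#'   `time`, `atp`, `ratio_true`), `time`, `acq`, `sensor`, `seed`.
#' @export
render_image_stack <- function(sims, compartment = "mito", sensor = NULL,
                               acq = acquisition_model(), height = 64,
                               width = 64, radius_range = c(6, 9),
                               expression_levels = 1, seed = 1L,
                               max_tries = 200) {
  n <- length(sims)
  stopifnot(n >= 1)
  if (is.null(sensor)) sensor <- default_sensor(compartment)
  expression_levels <- rep_len(expression_levels, n)
  times <- sims[[1]]$time
  if (!all(vapply(sims, function(s) identical(s$time, times), logical(1))))
    stop("all sims must share one time grid")
  nt <- length(times)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  # place non-overlapping ellipses
  mask <- matrix(0L, height, width)
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      a <- stats::runif(1, radius_range[1], radius_range[2])
      b <- stats::runif(1, radius_range[1], radius_range[2])
      cx <- stats::runif(1, b + 2, width - b - 1)
      cy <- stats::runif(1, a + 2, height - a - 1)
      yy <- matrix(seq_len(height), height, width)
      xx <- matrix(seq_len(width), height, width, byrow = TRUE)
      inside <- ((yy - cy) / a)^2 + ((xx - cx) / b)^2 <= 1
      # one-pixel clearance between cells
      dil <- ((yy - cy) / (a + 1.5))^2 + ((xx - cx) / (b + 1.5))^2 <= 1
      if (!any(mask[dil] > 0)) {
        mask[inside] <- i
        cells[[i]] <- inside
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place cell ", i, " without overlap")
  }

  atp_of <- function(s) switch(compartment, cyto = s$atp_c,
                               mito = s$atp_m, er = s$atp_er)
  frames <- array(0, dim = c(nt, height, width, 2))
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    atp <- atp_of(sims[[i]])
    f <- occupancy(atp, sensor)
    mu <- channel_means(f, acq, expression_levels[i])
    cfp_t <- mu$cfp * exp(-acq$bleach_rate_donor * times)
    yfp_t <- mu$yfp * exp(-acq$bleach_rate_acceptor * times)
    idx <- which(cells[[i]], arr.ind = TRUE)
    for (k in seq_len(nt)) {
      frames[k, , , 1][idx] <- cfp_t[k]
      frames[k, , , 2][idx] <- yfp_t[k]
    }
    truth[[i]] <- data.frame(time = times, atp = atp,
                             ratio_true = yfp_t / cfp_t)
  }
  frames[, , , 1] <- frames[, , , 1] + acq$bg_cfp
  frames[, , , 2] <- frames[, , , 2] + acq$bg_yfp
  if (acq$noise_sd > 0)
    frames <- frames + stats::rnorm(length(frames), 0, acq$noise_sd)

  structure(list(frames = frames, truth_masks = mask, truth_traces = truth,
                 time = times, acq = acq, sensor = sensor, seed = seed),
            class = "synthetic_stack")
}

#' Segment cell ROIs from an image stack
#'
#' Otsu threshold on the temporal-mean image of one channel, followed by
#' connected-component labelling; components smaller than `min_area` pixels
#' are dropped and labels renumbered contiguously.
#'
#' @param stack a `synthetic_stack` or a T x H x W x 2 array.
#' @param channel channel used for segmentation (2 = YFP, default).
#' @param min_area minimum ROI area (pixels).
#' @return Integer label matrix (H x W), background 0.
#' @export
segment_rois <- function(stack, channel = 2, min_area = 20) {
  frames <- if (inherits(stack, "synthetic_stack")) stack$frames else stack
  stopifnot(length(dim(frames)) == 4)
  avg <- apply(frames[, , , channel, drop = FALSE], c(2, 3), mean)
  rng <- range(avg)
  if (diff(rng) <= .Machine$double.eps * max(abs(rng), 1))
    stop("segment_rois: no foreground (blank image)")
  scaled <- (avg - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  bw <- scaled > th
  if (!any(bw)) stop("segment_rois: no foreground above threshold")
  lab <- EBImage::bwlabel(EBImage::Image(bw))
  lab <- EBImage::imageData(lab)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  if (!length(keep)) stop("segment_rois: no ROI larger than min_area")
  relab <- integer(length(sizes))
  relab[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  sel <- lab > 0
  out[sel] <- relab[lab[sel]]
  out
}

#' Extract per-ROI mean-intensity traces from a stack
#'
#' For each ROI label and frame, the mean pixel intensity in each channel;
#' the background estimate attached to each trace is the per-frame median
#' over background (label 0) pixels.
#'
#' @param stack a `synthetic_stack` or T x H x W x 2 array.
#' @param mask integer label matrix; defaults to the stack's truth mask.
#' @param time frame times; defaults to the stack's time grid.
#' @param compartment stored on the returned traces.
#' @return List of [dual_channel_trace()] objects, one per label.
#' @export
extract_roi_traces <- function(stack, mask = NULL, time = NULL,
                               compartment = "mito") {
  if (inherits(stack, "synthetic_stack")) {
    if (is.null(mask)) mask <- stack$truth_masks
    if (is.null(time)) time <- stack$time
    frames <- stack$frames
  } else frames <- stack
  stopifnot(length(dim(frames)) == 4)
  nt <- dim(frames)[1]
  if (is.null(time)) time <- seq_len(nt)
  labels <- sort(unique(mask[mask > 0]))
  if (!length(labels)) stop("extract_roi_traces: mask has no ROIs")
  bg_sel <- mask == 0
  bg_cfp <- bg_yfp <- numeric(nt)
  for (k in seq_len(nt)) {
    bg_cfp[k] <- stats::median(frames[k, , , 1][bg_sel])
    bg_yfp[k] <- stats::median(frames[k, , , 2][bg_sel])
  }
  lapply(labels, function(l) {
    sel <- mask == l
    if (!any(sel)) stop("empty ROI ", l)
    cfp <- yfp <- numeric(nt)
    for (k in seq_len(nt)) {
      cfp[k] <- mean(frames[k, , , 1][sel])
      yfp[k] <- mean(frames[k, , , 2][sel])
    }
    dual_channel_trace(time = time, cfp = cfp, yfp = yfp,
                       bg_cfp_est = bg_cfp, bg_yfp_est = bg_yfp,
                       cell_id = sprintf("roi_%02d", l),
                       compartment = compartment)
  })
}

#' Synthetic two-channel colocalization fixture
#'
#' Builds a pair of single-channel images whose above-background supports
#' overlap in a known pixel set, together with ground-truth Manders-type
#' fractions computed by direct pixel counting. Used to validate the
#' colocalization module against construction.
#'
#' @param size image side length (pixels).
#' @param overlap_fraction fraction of each channel's foreground pixels
#'   shared with the other channel, in `[0, 1]`.
#' @param n_fg foreground pixels per channel.
#' @param fg,bg foreground/background mean intensities.
#' @param noise_sd additive Gaussian noise.
#' @param seed integer seed.
#' @return List with `ch1`, `ch2` (matrices), `truth` (list `m1`, `m2`,
#'   `overlap_fraction`), and the foreground index sets.
#' @export
render_coloc_pair <- function(size = 64, overlap_fraction = 0.5, n_fg = 400,
                              fg = 100, bg = 10, noise_sd = 0, seed = 1L) {
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stop("overlap_fraction must lie in [0, 1]")
  n_pix <- size * size
  n_shared <- round(overlap_fraction * n_fg)
  if (2 * n_fg - n_shared > n_pix) stop("image too small for requested supports")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  pix <- sample.int(n_pix, 2 * n_fg - n_shared)
  shared <- pix[seq_len(n_shared)]
  only1 <- pix[seq_len(n_fg - n_shared) + n_shared]
  only2 <- pix[seq_len(n_fg - n_shared) + n_fg]
  ch1 <- matrix(bg, size, size); ch2 <- matrix(bg, size, size)
  ch1[c(shared, only1)] <- fg
  ch2[c(shared, only2)] <- fg
  if (noise_sd > 0) {
    ch1 <- ch1 + stats::rnorm(n_pix, 0, noise_sd)
    ch2 <- ch2 + stats::rnorm(n_pix, 0, noise_sd)
  }
  # ground truth by literal pixel counting on the construction
  s1 <- c(shared, only1); s2 <- c(shared, only2)
  m1 <- sum(ch1[intersect(s1, s2)]) / sum(ch1[s1])
  m2 <- sum(ch2[intersect(s1, s2)]) / sum(ch2[s2])
  list(ch1 = ch1, ch2 = ch2,
       truth = list(m1 = m1, m2 = m2, overlap_fraction = overlap_fraction),
       fg1 = s1, fg2 = s2)
}

#' Write / read an image stack as multi-page TIFF
#'
#' Pages are ordered frame-major with channels interleaved (axis order
#' TCYX): page `2*(t-1) + c` holds frame `t`, channel `c` (1 = CFP,
#' 2 = YFP). Intensities (arbitrary counts) are stored as 32-bit floats
#' divided by a fixed scale of 2^16, and rescaled on read; counts must
#' therefore stay below 65536.
#'
#' @param stack a `synthetic_stack` or T x H x W x 2 array.
#' @param path file path.
#' @return `read_stack_tiff` returns a T x H x W x 2 array.
#' @export
write_stack_tiff <- function(stack, path) {
  frames <- if (inherits(stack, "synthetic_stack")) stack$frames else stack
  nt <- dim(frames)[1]
  scale <- 65536
  if (max(frames) > scale) stop("intensities exceed the storage scale 2^16")
  pages <- vector("list", 2 * nt)
  for (k in seq_len(nt)) {
    pages[[2 * k - 1]] <- pmax(frames[k, , , 1], 0) / scale
    pages[[2 * k]] <- pmax(frames[k, , , 2], 0) / scale
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  np <- length(pages)
  if (np %% 2 != 0) stop("expected an even number of pages (TCYX, 2 channels)")
  scale <- 65536
  nt <- np / 2
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  frames <- array(0, dim = c(nt, h, w, 2))
  for (k in seq_len(nt)) {
    frames[k, , , 1] <- pages[[2 * k - 1]] * scale
    frames[k, , , 2] <- pages[[2 * k]] * scale
  }
  frames
}
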