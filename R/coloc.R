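#' Two-channel image pair for colocalization analysis
#'
#' @param ch1,ch2 same-shape non-negative intensity matrices (channel 1 =
#'   GFP-type label, channel 2 = mCherry-type label).
#' @param mask logical analysis region (e.g. a cell outline); default: the
#'   whole image.
#' @return Object of class `image_pair`.
#' @export
image_pair <- function(ch1, ch2, mask = NULL) {
  stopifnot(is.matrix(ch1), is.matrix(ch2))
  if (!identical(dim(ch1), dim(ch2))) stop("channel shapes differ")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(ch1), ncol(ch1))
  if (!identical(dim(mask), dim(ch1))) stop("mask shape differs")
  if (!any(mask)) stop("mask is empty")
  if (min(ch1[mask]) < 0 || min(ch2[mask]) < 0)
    stop("intensities must be >= 0")
  structure(list(ch1 = ch1, ch2 = ch2, mask = mask), class = "image_pair")
}

#' Pearson colocalization coefficient (unthresholded)
#'
#' Standard Pearson correlation of the two channels over the masked pixels,
#' computed on unthresholded data.
#'
#' @param pair an [image_pair()].
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
coloc_pearson <- function(pair) {
  x <- pair$ch1[pair$mask]; y <- pair$ch2[pair$mask]
  if (length(x) < 2) stop("need >= 2 pixels")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in a channel")
  stats::cor(x, y)
}

# orthogonal (total-least-squares) regression ch2 = a*ch1 + b
tls_line <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  cv <- stats::cov(cbind(x, y))
  e <- eigen(cv, symmetric = TRUE)
  v <- e$vectors[, 1]
  if (abs(v[1]) < .Machine$double.eps) stop("degenerate orthogonal fit")
  a <- v[2] / v[1]
  c(a = a, b = my - a * mx)
}

#' Costes automatic thresholds
#'
#' Implements the Costes threshold search: fit the orthogonal
#' (total-least-squares) regression `ch2 = a * ch1 + b` over the masked
#' pixels, then scan the channel-1 threshold `t1` downward from the channel
#' maximum with `t2 = a * t1 + b`, and keep the largest `t1` for which the
#' Pearson coefficient of the pixels *below* both thresholds is <= 0 (the
#' below-threshold population is uncorrelated). If the scan exhausts the
#' range the channel minimum is returned with a warning flag.
#'
#' @param pair an [image_pair()].
#' @param step scan step; default 1 intensity unit for integer-valued
#'   images, (max - min)/1000 otherwise.
#' @return List `t1`, `t2`, `a`, `b`, `exhausted`.
#' @export
costes_thresholds <- function(pair, step = NULL) {
  x <- pair$ch1[pair$mask]; y <- pair$ch2[pair$mask]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in a channel")
  ab <- tls_line(x, y)
  if (is.null(step)) {
    step <- if (all(x == round(x)) && all(y == round(y))) 1
            else (max(x) - min(x)) / 1000
  }
  t1 <- max(x)
  repeat {
    t2 <- ab[["a"]] * t1 + ab[["b"]]
    below <- x < t1 & y < t2
    if (sum(below) >= 2) {
      xb <- x[below]; yb <- y[below]
      if (stats::sd(xb) > 0 && stats::sd(yb) > 0 &&
          stats::cor(xb, yb) <= 0)
        return(list(t1 = t1, t2 = t2, a = ab[["a"]], b = ab[["b"]],
                    exhausted = FALSE))
    }
    t1 <- t1 - step
    if (t1 < min(x)) break
  }
  t1 <- min(x)
  list(t1 = t1, t2 = ab[["a"]] * t1 + ab[["b"]], a = ab[["a"]],
       b = ab[["b"]], exhausted = TRUE)
}

#' Manders colocalization coefficients on thresholded images
#'
#' `M1` is the fraction of channel-1 intensity (over pixels above `t1`)
#' residing in pixels where channel 2 is also above `t2`; `M2` is the
#' symmetric quantity. The default dialect requires both channels above
#' threshold in the numerator (the common Costes convention); the
#' `"above_other"` dialect conditions the numerator only on the *other*
#' channel's threshold.
#'
#' @param pair an [image_pair()].
#' @param t1,t2 channel thresholds (e.g. from [costes_thresholds()]).
#' @param dialect `"both_above"` (default) or `"above_other"`.
#' @return List `m1`, `m2` (each in `[0, 1]`, `NA` with a flag when a
#'   denominator is empty), `n_pixels_analyzed`.
#' @export
manders <- function(pair, t1, t2, dialect = c("both_above", "above_other")) {
  dialect <- match.arg(dialect)
  x <- pair$ch1[pair$mask]; y <- pair$ch2[pair$mask]
  a1 <- x > t1; a2 <- y > t2
  num1 <- if (dialect == "both_above") a1 & a2 else a2
  num2 <- if (dialect == "both_above") a1 & a2 else a1
  d1 <- sum(x[a1]); d2 <- sum(y[a2])
  m1 <- if (d1 > 0) sum(x[a1 & num1]) / d1 else NA_real_
  m2 <- if (d2 > 0) sum(y[a2 & num2]) / d2 else NA_real_
  list(m1 = m1, m2 = m2, undefined = d1 <= 0 || d2 <= 0,
       n_pixels_analyzed = length(x))
}

#' Full colocalization analysis of an image pair
#'
#' Pearson on unthresholded pixels, Costes thresholds, and Manders M1/M2 on
#' the thresholded images, as in standard two-channel colocalization
#' workflows.
#'
#' @param pair an [image_pair()].
#' @param dialect Manders dialect, see [manders()].
#' @return Object of class `coloc_result`: list `pearson`, `t1`, `t2`, `a`,
#'   `b`, `m1`, `m2`, `n_pixels_analyzed`, `thresholds_exhausted`.
#' @export
coloc_analysis <- function(pair, dialect = "both_above") {
  p <- coloc_pearson(pair)
  th <- costes_thresholds(pair)
  m <- manders(pair, th$t1, th$t2, dialect = dialect)
  structure(list(pearson = p, t1 = th$t1, t2 = th$t2, a = th$a, b = th$b,
                 m1 = m$m1, m2 = m$m2,
                 n_pixels_analyzed = m$n_pixels_analyzed,
                 thresholds_exhausted = th$exhausted),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(
    "<coloc_result> pearson=%.4f t1=%.3g t2=%.3g M1=%.4f M2=%.4f (n=%d)\n",
    x$pearson, x$t1, x$t2, x$m1, x$m2, x$n_pixels_analyzed))
  invisible(x)
}

#' Write a colocalization result as JSON
#'
#' @param result a `coloc_result`.
#' @param path output file.
#' @export
write_coloc_json <- function(result, path) {
  jsonlite::write_json(c(list(format_version = 1L), unclass(result)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
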