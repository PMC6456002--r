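#' Group summary statistics
#'
#' Mean, standard deviation (n - 1 denominator), standard error of the mean
#' and n. With a single value, SD and SEM are 0 by convention and the result
#' is flagged.
#'
#' @param values numeric vector (n >= 1).
#' @return Named list: `mean`, `sd`, `sem`, `n`, `degenerate`.
#' @export
summarize_group <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 1) stop("summarize_group: empty input")
  s <- if (n > 1) stats::sd(values) else 0
  list(mean = mean(values), sd = s, sem = s / sqrt(n), n = n,
       degenerate = n < 2)
}

#' Build the two-axis metabolic fingerprint table
#'
#' One point per cell: the maximal mitochondrial ratio change upon hexose
#' removal (`delta_glc`, x axis) against the maximal change upon oligomycin
#' (`delta_oligo`, y axis), both in normalized ratio units, with per-group
#' means, SD, SEM and n. The two axes probe glycolytic and oxidative ATP
#' supply respectively, and together they place each cell's metabolic
#' setting.
#'
#' @param features data.frame with columns `cell_id`, `delta_glc`,
#'   `delta_oligo` (stacked [extract_features()] rows); rows failing QC
#'   (`qc_pass == FALSE`) are dropped.
#' @param groups per-cell group labels (recycled if length 1).
#' @return Object of class `fingerprint_table`: list with `points`
#'   (data.frame `cell_id`, `group`, `delta_glc`, `delta_oligo`) and
#'   `summary` (one row per group and axis).
#' @export
build_fingerprint <- function(features, groups = "all") {
  stopifnot(is.data.frame(features))
  if (!all(c("delta_glc", "delta_oligo") %in% names(features)))
    stop("features must contain delta_glc and delta_oligo")
  groups <- rep_len(groups, nrow(features))
  keep <- rep(TRUE, nrow(features))
  if ("qc_pass" %in% names(features)) keep <- features$qc_pass
  pts <- data.frame(cell_id = features$cell_id[keep], group = groups[keep],
                    delta_glc = features$delta_glc[keep],
                    delta_oligo = features$delta_oligo[keep],
                    stringsAsFactors = FALSE)
  if (any(!is.finite(pts$delta_glc)) || any(!is.finite(pts$delta_oligo)))
    stop("every cell needs both delta_glc and delta_oligo")
  summ <- do.call(rbind, lapply(split(pts, pts$group), function(g) {
    do.call(rbind, lapply(c("delta_glc", "delta_oligo"), function(ax) {
      s <- summarize_group(g[[ax]])
      data.frame(group = g$group[1], axis = ax, mean = s$mean, sd = s$sd,
                 sem = s$sem, n = s$n, stringsAsFactors = FALSE)
    }))
  }))
  rownames(summ) <- NULL
  structure(list(points = pts, summary = summ), class = "fingerprint_table")
}

#' @export
print.fingerprint_table <- function(x, ...) {
  cat("<fingerprint_table> ", nrow(x$points), " cells, ",
      length(unique(x$points$group)), " group(s)\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Classify the metabolic setting of each cell
#'
#' Default rule: a cell is `glycolytic` when its glucose-removal response
#' dominates (`|delta_glc| > |delta_oligo|` and `delta_glc < -tau`),
#' `oxidative` when its oligomycin response dominates (`|delta_oligo| >
#' |delta_glc|` and `delta_oligo < -tau`), and `intermediate` otherwise.
#' `tau` is this package's operational threshold in normalized ratio units.
#' The alternative `"kmeans"` method partitions the standardized coordinates
#' into two clusters with deterministic seeding and labels the cluster with
#' the more negative mean `delta_glc` glycolytic.
#'
#' @param fp a [build_fingerprint()] table (or its `points` data.frame).
#' @param method `"rule"` (default) or `"kmeans"`.
#' @param tau response threshold (normalized ratio units).
#' @return Character vector of labels, one per cell.
#' @export
classify_setting <- function(fp, method = c("rule", "kmeans"), tau = 0.1) {
  method <- match.arg(method)
  pts <- if (inherits(fp, "fingerprint_table")) fp$points else fp
  if (nrow(pts) < 2) stop("classify_setting: need >= 2 cells")
  if (method == "rule") {
    g <- abs(pts$delta_glc) > abs(pts$delta_oligo) & pts$delta_glc < -tau
    o <- abs(pts$delta_oligo) > abs(pts$delta_glc) & pts$delta_oligo < -tau
    out <- rep("intermediate", nrow(pts))
    out[g] <- "glycolytic"
    out[o] <- "oxidative"
    out
  } else {
    xy <- scale(cbind(pts$delta_glc, pts$delta_oligo))
    # deterministic seeding: the two mutually most distant points
    d <- as.matrix(stats::dist(xy))
    ij <- which(d == max(d), arr.ind = TRUE)[1, ]
    km <- stats::kmeans(xy, centers = xy[c(ij[1], ij[2]), , drop = FALSE])
    means_glc <- tapply(pts$delta_glc, km$cluster, mean)
    glyc_cl <- as.integer(names(which.min(means_glc)))
    ifelse(km$cluster == glyc_cl, "glycolytic", "oxidative")
  }
}

#' Compare groups of per-cell measurements
#'
#' Two groups: unpaired two-sample Student's t test (equal variance by
#' default, Welch by flag). Three or more: one-way ANOVA followed by Tukey's
#' honest significant difference for all pairwise comparisons.
#'
#' @param samples named list of numeric vectors (each n >= 2).
#' @param var_equal classical equal-variance t test (default TRUE).
#' @return For two groups: list `method`, `statistic` (t), `df`, `p_value`,
#'   `estimate` (difference of means). For more: list `method`, `f`,
#'   `df`, `p_value` (ANOVA), and `tukey` (data.frame with pairwise
#'   `diff`, `lwr`, `upr`, `p_adj`).
#' @export
compare_groups <- function(samples, var_equal = TRUE) {
  if (!is.list(samples) || length(samples) < 2)
    stop("compare_groups: need >= 2 groups")
  if (any(vapply(samples, length, integer(1)) < 2))
    stop("compare_groups: every group needs n >= 2")
  if (is.null(names(samples)))
    names(samples) <- paste0("group", seq_along(samples))
  if (length(samples) == 2) {
    tt <- stats::t.test(samples[[1]], samples[[2]], var.equal = var_equal)
    list(method = if (var_equal) "student_t" else "welch_t",
         statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value,
         estimate = mean(samples[[1]]) - mean(samples[[2]]))
  } else {
    df <- data.frame(
      value = unlist(samples, use.names = FALSE),
      group = factor(rep(names(samples), vapply(samples, length, integer(1)))))
    fit <- stats::aov(value ~ group, data = df)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$group
    tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                        lwr = tk[, "lwr"], upr = tk[, "upr"],
                        p_adj = tk[, "p adj"], row.names = NULL,
                        stringsAsFactors = FALSE)
    list(method = "anova_tukey", f = an[["F value"]][1],
         df = c(an[["Df"]][1], an[["Df"]][2]),
         p_value = an[["Pr(>F)"]][1], tukey = tukey)
  }
}

#' Write fingerprint outputs
#'
#' `write_fingerprint_csv` writes the per-cell points;
#' `write_group_summary_json` writes the per-group summary (with a format
#' version and a note that axes are in normalized ratio units).
#'
#' @param fp a `fingerprint_table`.
#' @param path output file.
#' @export
write_fingerprint_csv <- function(fp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# atpfret fingerprint format_version=1 units=normalized_ratio",
             con)
  utils::write.csv(fp$points, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fingerprint_csv
#' @export
write_group_summary_json <- function(fp, path) {
  jsonlite::write_json(
    list(format_version = 1L, units = "normalized_ratio",
         summary = fp$summary),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
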