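## k-means clustering of baseline-normalized single-cell response
## trajectories, cluster summaries, and grower/non-grower contrasts.

#' Resample normalized traces onto a common time grid
#'
#' Linear interpolation of each cell's normalized ratio onto a shared grid,
#' producing the cells x timepoints matrix that k-means operates on. By
#' default the grid is the post-perturbation (`time >= 0`) frame grid of the
#' first cell. Cells covering less than `min_coverage` of the grid span are
#' excluded with a QC record; remaining edge values are clipped to the
#' nearest observed frame.
#'
#' @param normalized a `normalized_traces` data frame
#'   (see [normalize_baseline()]).
#' @param grid numeric vector of times (minutes), or `NULL` for the default.
#' @param min_coverage minimum fraction of the grid span a trace must cover.
#' @return matrix (rows = cells, columns = grid times) with an `excluded`
#'   attribute listing dropped cells.
#' @export
resample_traces <- function(normalized, grid = NULL, min_coverage = 0.5) {
  sp <- split(normalized[c("time_min", "normalized_ratio")],
              normalized$cell_id)
  if (is.null(grid)) {
    t1 <- sp[[1]]$time_min
    grid <- sort(t1[t1 >= 0])
  }
  span <- diff(range(grid))
  rows <- lapply(sp, function(tr) {
    cover <- min(max(tr$time_min), max(grid)) - max(min(tr$time_min), min(grid))
    if (cover < min_coverage * span) return(NULL)
    stats::approx(tr$time_min, tr$normalized_ratio, xout = grid,
                  rule = 2)$y
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) stop("no trace covers the requested grid")
  m <- do.call(rbind, rows[keep])
  rownames(m) <- names(sp)[keep]
  colnames(m) <- format(grid, trim = TRUE)
  attr(m, "grid") <- grid
  attr(m, "excluded") <- names(sp)[!keep]
  if (any(!keep)) {
    message(sum(!keep), " trace(s) covered < ", min_coverage * 100,
            "% of the grid and were excluded")
  }
  m
}

#' Cluster response trajectories with k-means
#'
#' Euclidean k-means on the trace matrix, best of `n_restarts` random starts
#' by within-cluster sum of squares. Clusters are canonically relabeled in
#' descending order of mean final normalized FRET (mean over the last three
#' grid points of member traces), so cluster 1 is always the
#' highest-plateau response class.
#'
#' @param mat cells x timepoints matrix from [resample_traces()].
#' @param k number of clusters.
#' @param seed integer seed (restart initialization).
#' @param n_restarts random restarts.
#' @param iter_max k-means iteration cap.
#' @return object of class `cluster_result`: `labels` (named per-cell,
#'   canonical 1..k), `k`, `centroids` (canonical order), `inertia`,
#'   `cluster_final` (per-cluster mean final normalized FRET), `sizes`.
#' @export
cluster_traces <- function(mat, k = 3, seed = 1L, n_restarts = 25,
                           iter_max = 300) {
  n <- nrow(mat)
  if (k < 1 || k > n) stop("k must be between 1 and the number of cells")
  if (k > 1 && nrow(unique(mat)) < k) {
    stop("fewer distinct traces than clusters requested")
  }
  set.seed(seed)
  km <- if (k == n) {
    ## one cell per cluster: the unique zero-inertia partition
    list(cluster = seq_len(n), centers = mat, tot.withinss = 0)
  } else {
    stats::kmeans(mat, centers = k, nstart = n_restarts,
                  iter.max = iter_max)
  }
  nc <- ncol(mat)
  final_per_cell <- rowMeans(mat[, max(1, nc - 2):nc, drop = FALSE])
  cluster_final <- tapply(final_per_cell, km$cluster, mean)
  ord <- order(cluster_final, decreasing = TRUE)  # canonical order
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  labels <- relabel[km$cluster]
  names(labels) <- rownames(mat)
  structure(list(labels = labels, k = k,
                 centroids = km$centers[ord, , drop = FALSE],
                 inertia = km$tot.withinss,
                 cluster_final = as.numeric(cluster_final[ord]),
                 sizes = as.integer(table(factor(labels, levels = seq_len(k))))),
            class = "cluster_result")
}

#' Per-cluster feature summaries
#'
#' @param result a `cluster_result`.
#' @param features per-cell feature table from [fret_pipeline()].
#' @return data frame with one row per cluster: n and mean/SD of basal FRET,
#'   expression proxy, final FRET, delta normalized FRET and maximal slope.
#' @export
summarize_clusters <- function(result, features) {
  idx <- match(names(result$labels), features$cell_id)
  if (anyNA(idx)) stop("features missing for some clustered cells")
  f <- features[idx, , drop = FALSE]
  cl <- factor(result$labels, levels = seq_len(result$k))
  one <- function(v) {
    data.frame(mean = tapply(v, cl, mean), sd = tapply(v, cl, stats::sd))
  }
  cols <- c("basal_fret", "expression_proxy", "final_fret",
            "delta_norm_fret", "max_slope")
  out <- data.frame(cluster = seq_len(result$k),
                    n = as.integer(table(cl)))
  for (cn in cols) {
    s <- one(f[[cn]])
    out[[paste0(cn, "_mean")]] <- as.numeric(s$mean)
    out[[paste0(cn, "_sd")]] <- as.numeric(s$sd)
  }
  rownames(out) <- NULL
  out
}

#' Grower fraction per cluster
#'
#' @param result a `cluster_result`.
#' @param grower named logical vector (or data frame with `cell_id` and
#'   `grower`) of external growth labels.
#' @return data frame (cluster, n, n_grower, grower_fraction); the fraction
#'   is `NA` for empty clusters.
#' @export
composition_histogram <- function(result, grower) {
  if (is.data.frame(grower)) {
    grower <- stats::setNames(grower$grower, grower$cell_id)
  }
  g <- grower[names(result$labels)]
  if (anyNA(g)) stop("growth labels missing for some clustered cells")
  cl <- factor(result$labels, levels = seq_len(result$k))
  n <- as.integer(table(cl))
  n_grower <- as.integer(tapply(g, cl, sum, default = 0L))
  data.frame(cluster = seq_len(result$k), n = n, n_grower = n_grower,
             grower_fraction = ifelse(n > 0, n_grower / n, NA_real_))
}

#' Two-group feature contrast
#'
#' Two-sample t-test on a per-cell feature. The classical pooled-variance
#' Student form is the default; Welch's unequal-variance form is available
#' with `var_equal = FALSE`.
#'
#' @param values numeric feature values.
#' @param groups two-level factor or vector of group labels.
#' @param var_equal pooled-variance Student test (default `TRUE`).
#' @return object of class `group_contrast`: group means/SDs/n, `t`,
#'   `p_value`, `df`.
#' @export
compare_groups <- function(values, groups, var_equal = TRUE) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  if (any(table(groups) < 2)) stop("each group needs >= 2 observations")
  tt <- stats::t.test(values ~ groups, var.equal = var_equal)
  sp <- split(values, groups)
  structure(list(
    groups = levels(groups),
    mean = vapply(sp, mean, numeric(1)),
    sd = vapply(sp, stats::sd, numeric(1)),
    n = vapply(sp, length, integer(1)),
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, var_equal = var_equal
  ), class = "group_contrast")
}

#' @export
print.group_contrast <- function(x, ...) {
  cat(sprintf("Two-sample t-test (%s variance)\n",
              if (x$var_equal) "pooled" else "Welch"))
  for (i in 1:2) {
    cat(sprintf("  %s: %.3g +/- %.3g (n = %d)\n",
                x$groups[i], x$mean[i], x$sd[i], x$n[i]))
  }
  cat(sprintf("  t = %.3g, df = %.4g, p = %.3g\n", x$t, x$df, x$p_value))
  invisible(x)
}

#' Elbow / silhouette-style diagnostics for choosing k
#'
#' Reports k-means inertia for a range of k to assist the (manual) choice of
#' the cluster count; no automatic selection is performed.
#'
#' @param mat trace matrix.
#' @param k_range candidate cluster counts.
#' @param seed,n_restarts passed to [cluster_traces()].
#' @return data frame (k, inertia).
#' @export
cluster_diagnostics <- function(mat, k_range = 1:6, seed = 1L,
                                n_restarts = 10) {
  data.frame(k = k_range,
             inertia = vapply(k_range, function(k) {
               cluster_traces(mat, k, seed = seed,
                              n_restarts = n_restarts)$inertia
             }, numeric(1)))
}
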