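#' ISODATA (iso-cluster) parameters
#'
#' Controls for the deterministic migrating-means classifier. Defaults
#' mirror common iso-cluster tool settings; all are overridable.
#'
#' @param k Number of clusters requested (the flower-mapping workflow uses
#'   5: one soil, one green-vegetation and three flower clusters of varying
#'   yellowness).
#' @param max_iterations Iteration cap for the migrating-means loop.
#' @param change_tolerance Convergence threshold: stop once fewer than this
#'   fraction of pixels switch cluster between iterations.
#' @param min_cluster_size Clusters smaller than this pixel count are merged
#'   into their nearest-mean neighbour after convergence.
#' @param sample_interval Pixel stride used when recomputing centroids
#'   (1 = every valid pixel). Assignment always covers all pixels.
#' @param seed Retained for optional randomized restarts; the default
#'   quantile initialization is deterministic and ignores it.
#' @return A list of class `iso_params`.
#' @export
iso_params <- function(k = 5L, max_iterations = 20L, change_tolerance = 0.001,
                       min_cluster_size = 20L, sample_interval = 1L,
                       seed = NULL) {
  if (k < 2L) rlang::abort("`k` must be at least 2")
  if (max_iterations < 1L) rlang::abort("`max_iterations` must be at least 1")
  if (change_tolerance < 0) rlang::abort("`change_tolerance` must be >= 0")
  structure(list(k = as.integer(k), max_iterations = as.integer(max_iterations),
                 change_tolerance = change_tolerance,
                 min_cluster_size = as.integer(min_cluster_size),
                 sample_interval = as.integer(sample_interval), seed = seed),
            class = "iso_params")
}

# Squared Euclidean distances between n x d data and k x d centroids.
dist_sq <- function(X, C) {
  if (ncol(X) == 1L) {
    outer(X[, 1], C[, 1], `-`)^2
  } else {
    n <- nrow(X)
    D <- matrix(0, n, nrow(C))
    for (kk in seq_len(nrow(C))) {
      D[, kk] <- rowSums((X - matrix(C[kk, ], n, ncol(X), byrow = TRUE))^2)
    }
    D
  }
}

# Core migrating-means loop on an n x d feature matrix. Deterministic:
# centroids start at the (i - 0.5)/k per-dimension quantiles of the data,
# assignment breaks ties toward the lowest centroid index, and empty
# clusters are re-seeded at the worst-fit pixel.
isodata_core <- function(X, params) {
  n <- nrow(X); d <- ncol(X)
  k_req <- params$k
  n_distinct <- nrow(unique(X))
  warn_flag <- n_distinct < k_req
  k <- min(k_req, n_distinct)
  if (k == 1L) {
    return(list(labels = rep(1L, n), means = matrix(colMeans(X), 1, d),
                sizes = n, iterations = 0L, converged = TRUE,
                warning = TRUE, wss_trace = 0,
                wss = sum(dist_sq(X, matrix(colMeans(X), 1, d)))))
  }
  C <- vapply(seq_len(d), function(j) {
    stats::quantile(X[, j], probs = (seq_len(k) - 0.5) / k, type = 7, names = FALSE)
  }, numeric(k))
  C <- matrix(C, k, d)

  stride <- max(1L, params$sample_interval)
  sub <- seq(1L, n, by = stride)
  labels <- integer(n)
  wss_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < params$max_iterations) {
    iter <- iter + 1L
    D <- dist_sq(X, C)
    new_labels <- max.col(-D, ties.method = "first")
    d_own <- D[cbind(seq_len(n), new_labels)]
    # re-seed empty clusters at the pixel farthest from its centroid
    empties <- setdiff(seq_len(k), unique(new_labels))
    for (e in empties) {
      far <- which.max(d_own)
      C[e, ] <- X[far, ]
      new_labels[far] <- e
      d_own[far] <- 0
    }
    wss_trace <- c(wss_trace, sum(D[cbind(seq_len(n), new_labels)]))
    frac_changed <- mean(new_labels != labels)
    labels <- new_labels
    for (kk in seq_len(k)) {
      members <- sub[labels[sub] == kk]
      if (length(members)) C[kk, ] <- colMeans(X[members, , drop = FALSE])
    }
    if (iter > 1L && frac_changed < params$change_tolerance) {
      converged <- TRUE
      break
    }
  }
  # merge undersized clusters into the nearest-mean neighbour
  repeat {
    sizes <- tabulate(labels, nbins = k)
    keep <- sizes > 0L
    small <- which(keep & sizes < params$min_cluster_size)
    if (!length(small) || sum(keep) <= 1L) break
    s <- small[which.min(sizes[small])]
    others <- setdiff(which(keep), s)
    if (!length(others)) break
    tgt <- others[which.min(rowSums((C[others, , drop = FALSE] -
                    matrix(C[s, ], length(others), d, byrow = TRUE))^2))]
    labels[labels == s] <- tgt
    C[tgt, ] <- colMeans(X[labels == tgt, , drop = FALSE])
    C[s, ] <- NA_real_
  }
  # relabel surviving clusters by ascending mean (first feature), and
  # recompute means exactly from members so the stored means are the
  # member means regardless of stride or merge history
  surv <- sort(unique(labels))
  mm <- vapply(surv, function(kk) colMeans(X[labels == kk, , drop = FALSE]),
               numeric(d))
  means <- if (d == 1L) matrix(mm, ncol = 1L) else t(mm)
  ord <- order(means[, 1])
  relab <- integer(max(surv))
  relab[surv[ord]] <- seq_along(surv)
  labels <- relab[labels]
  means <- means[ord, , drop = FALSE]
  sizes <- tabulate(labels, nbins = length(surv))
  wss <- sum(dist_sq(X, means)[cbind(seq_len(n), labels)])
  list(labels = labels, means = means, sizes = sizes, iterations = iter,
       converged = converged, warning = warn_flag || length(surv) < k_req,
       wss_trace = wss_trace, wss = wss)
}

#' ISODATA classification of an index raster
#'
#' Unsupervised migrating-means clustering of the valid pixel values,
#' k-means-like but fully deterministic: centroids are initialized at
#' evenly spaced quantiles of the data, each pixel joins the centroid at
#' smallest Euclidean distance (ties to the lowest cluster index), means
#' migrate until fewer than `change_tolerance` of pixels switch, empty
#' clusters are re-seeded at the worst-fit pixel, and undersized clusters
#' are merged into their nearest neighbour after convergence. Output
#' cluster indices are sorted by ascending mean so cluster 1 is always the
#' darkest (lowest-index) cluster.
#'
#' @param index An [index_raster()] (or an `elevation_raster`; any
#'   single-band raster clusters on its values).
#' @param params An [iso_params()].
#' @return An object of class `cluster_map`: per-pixel integer labels in
#'   `1..k` (NA at nodata), cluster means, sizes, iteration count,
#'   convergence and degeneracy flags, and the within-cluster
#'   sum-of-squares trace.
#' @export
isodata_classify <- function(index, params = iso_params()) {
  if (!inherits(index, "osr_raster") || is.null(index$values)) {
    rlang::abort("`index` must be a single-band raster")
  }
  valid <- which(!index$mask)
  if (length(valid) < 1L) rlang::abort("no valid pixels to classify")
  X <- matrix(index$values[valid], ncol = 1)
  fit <- isodata_core(X, params)
  labels <- matrix(NA_integer_, nrow(index$values), ncol(index$values))
  labels[valid] <- fit$labels
  if (fit$warning) {
    rlang::warn(sprintf(
      "returning %d cluster(s) instead of the %d requested (degenerate values or merged undersized clusters)",
      length(fit$sizes), params$k))
  }
  structure(
    list(labels = labels, means = as.numeric(fit$means[, 1]),
         sizes = fit$sizes, iterations = fit$iterations,
         converged = fit$converged, degenerate = fit$warning,
         wss = fit$wss, wss_trace = fit$wss_trace,
         resolution = index$resolution, origin = index$origin,
         crs = index$crs),
    class = "cluster_map")
}

#' @export
print.cluster_map <- function(x, ...) {
  cat(sprintf("<cluster_map> %d clusters, %d iterations (%s), WSS %.6g\n",
              length(x$means), x$iterations,
              if (x$converged) "converged" else "iteration cap", x$wss))
  print(tibble::tibble(cluster = seq_along(x$means), mean = x$means, size = x$sizes))
  invisible(x)
}

#' NDYI class thresholds
#'
#' Cluster-mean thresholds that map clusters to semantic classes: a cluster
#' whose mean NDYI exceeds `flower_min` is flowering canopy; means within
#' `vegetation` are green vegetation; means within `soil` are bare soil.
#' The gap between the vegetation upper bound and `flower_min` is
#' unclassified by default (conservative flower counting), or snapped to
#' the nearest range under `gap_policy = "nearest"`.
#'
#' @param flower_min Flower threshold on the cluster-mean NDYI (default
#'   0.12).
#' @param vegetation Closed interval of vegetation cluster means.
#' @param soil Interval of soil cluster means; `[-1, -0.45)`, half-open at
#'   the vegetation boundary.
#' @param gap_policy `"unclassified"` (default) or `"nearest"`.
#' @return A list of class `class_thresholds`.
#' @export
class_thresholds <- function(flower_min = 0.12,
                             vegetation = c(-0.45, -0.15),
                             soil = c(-1, -0.45),
                             gap_policy = c("unclassified", "nearest")) {
  gap_policy <- match.arg(gap_policy)
  structure(list(flower_min = flower_min, vegetation = sort(vegetation),
                 soil = sort(soil), gap_policy = gap_policy),
            class = "class_thresholds")
}

OSR_CLASSES <- c("soil", "vegetation", "flower", "unclassified")

#' Group clusters into semantic classes
#'
#' Classification operates on cluster means, not per-pixel values: every
#' pixel inherits the class of its cluster. This is the point of clustering
#' before thresholding — whole clusters of varying flower yellowness are
#' grouped as flowers, rather than cutting pixels at a hard index value.
#'
#' @param clusters A `cluster_map` from [isodata_classify()].
#' @param thresholds A [class_thresholds()].
#' @return An object of class `class_map`: per-pixel factor-coded labels
#'   (`soil`, `vegetation`, `flower`, `unclassified`; NA at nodata), the
#'   per-class pixel counts, the cluster-to-class table and the thresholds
#'   used.
#' @export
assign_classes <- function(clusters, thresholds = class_thresholds()) {
  if (!inherits(clusters, "cluster_map")) rlang::abort("`clusters` must be a cluster_map")
  th <- thresholds
  classify_mean <- function(m) {
    if (m > th$flower_min) "flower"
    else if (m >= th$vegetation[1] && m <= th$vegetation[2]) "vegetation"
    else if (m >= th$soil[1] && m < th$soil[2]) "soil"
    else if (identical(th$gap_policy, "nearest") && m > th$vegetation[2] &&
             m <= th$flower_min) {
      if (abs(m - th$vegetation[2]) <= abs(m - th$flower_min)) "vegetation" else "flower"
    } else "unclassified"
  }
  cluster_class <- vapply(clusters$means, classify_mean, character(1))
  class_codes <- match(cluster_class, OSR_CLASSES)
  labels <- matrix(class_codes[clusters$labels], nrow(clusters$labels),
                   ncol(clusters$labels))
  counts <- stats::setNames(
    vapply(seq_along(OSR_CLASSES), function(i) sum(labels == i, na.rm = TRUE),
           integer(1)),
    OSR_CLASSES)
  structure(
    list(labels = labels, class_levels = OSR_CLASSES, class_counts = counts,
         cluster_table = tibble::tibble(
           cluster = seq_along(clusters$means),
           mean = clusters$means, size = clusters$sizes,
           class = cluster_class),
         thresholds = th,
         resolution = clusters$resolution, origin = clusters$origin,
         crs = clusters$crs),
    class = "class_map")
}

#' @export
print.class_map <- function(x, ...) {
  cat("<class_map> pixel counts:\n")
  print(x$class_counts)
  invisible(x)
}

#' Count pixels carrying a semantic class label
#'
#' @param class_map A `class_map` from [assign_classes()].
#' @param label One of `soil`, `vegetation`, `flower`, `unclassified`.
#' @return Integer pixel count.
#' @export
count_class_pixels <- function(class_map, label) {
  if (!inherits(class_map, "class_map")) rlang::abort("`class_map` must be a class_map")
  if (!label %in% class_map$class_levels) {
    rlang::abort(sprintf("unknown class label '%s' (expected one of: %s)",
                         label, paste(class_map$class_levels, collapse = ", ")))
  }
  unname(class_map$class_counts[[label]])
}
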