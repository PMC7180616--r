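# Concentric IoU between box dimensions (boxes placed at a common center).
# For circles dims are radii; for rects dims are (w, h) rows.
concentric_iou <- function(dims_a, dims_b, shape) {
  if (shape == "circle") {
    (pmin(dims_a, dims_b) / pmax(dims_a, dims_b))^2
  } else {
    a <- matrix(dims_a, ncol = 2)
    b <- matrix(dims_b, ncol = 2)
    n <- max(nrow(a), nrow(b))
    if (nrow(a) == 1L) a <- a[rep(1L, n), , drop = FALSE]
    if (nrow(b) == 1L) b <- b[rep(1L, n), , drop = FALSE]
    inter <- pmin(a[, 1], b[, 1]) * pmin(a[, 2], b[, 2])
    inter / (a[, 1] * a[, 2] + b[, 1] * b[, 2] - inter)
  }
}

check_dims <- function(dims, shape) {
  if (shape == "circle") {
    dims <- as.numeric(dims)
    if (any(!is.finite(dims)) || any(dims <= 0))
      stop_input("circle dimensions (radii) must be positive and finite")
    matrix(dims, ncol = 1)
  } else {
    if (is.null(dim(dims)) && length(dims) == 2L) dims <- rbind(dims)
    dims <- as.matrix(dims)
    dimnames(dims) <- NULL
    if (ncol(dims) != 2)
      stop_input("rect dimensions must be a 2-column (w, h) matrix")
    if (any(!is.finite(dims)) || any(dims <= 0))
      stop_input("rect dimensions must be positive and finite")
    dims
  }
}

dim_area <- function(dims, shape) {
  if (shape == "circle") pi * dims[, 1]^2 else dims[, 1] * dims[, 2]
}

#' IoU distance between box dimensions
#'
#' Distance used for anchor clustering: `1 - IoU` of the two boxes placed
#' concentrically, so that box pairs of similar size and shape are close
#' regardless of where they appear in the image. For circles this is
#' `1 - (min(r, r') / max(r, r'))^2`; for rectangles,
#' `1 - (min-w * min-h) / union-area`.
#'
#' @param dim_a,dim_b For `shape = "circle"`, positive radii; for
#'   `shape = "rect"`, `(w, h)` pairs (vectors or 2-column matrices).
#' @param shape `"circle"` or `"rect"`.
#' @return Distances in `[0, 1]`; 0 iff the dimensions are equal.
#' @export
iou_distance <- function(dim_a, dim_b, shape = c("circle", "rect")) {
  shape <- match.arg(shape)
  a <- check_dims(dim_a, shape)
  b <- check_dims(dim_b, shape)
  1 - concentric_iou(if (shape == "circle") a[, 1] else a,
                     if (shape == "circle") b[, 1] else b, shape)
}

#' Anchor set container
#'
#' Holds `k` prior anchor dimensions, sorted ascending by area, together
#' with their partition into three detection scales. Following the usual
#' multi-scale convention the smallest third of the anchors is assigned to
#' the finest-resolution scale (smallest stride) and the largest third to
#' the coarsest.
#'
#' @param dims Radii (circle) or 2-column `(w, h)` matrix (rect).
#' @param shape `"circle"` or `"rect"`.
#' @param mean_best_iou Optional clustering quality diagnostic to store.
#' @return An object of class `anchor_set`: a list with elements `shape`,
#'   `dims` (sorted), `scale_assignment` (list `fine`, `mid`, `coarse` of
#'   indices into `dims`) and `mean_best_iou`.
#' @export
anchor_set <- function(dims, shape = c("circle", "rect"), mean_best_iou = NULL) {
  shape <- match.arg(shape)
  dims <- check_dims(dims, shape)
  ord <- order(dim_area(dims, shape))
  dims <- dims[ord, , drop = FALSE]
  k <- nrow(dims)
  sizes <- rep(k %/% 3, 3) + c(rep(1, k %% 3), rep(0, 3 - k %% 3))
  idx <- split(seq_len(k), rep(1:3, sizes))
  structure(list(
    shape = shape,
    dims = if (shape == "circle") dims[, 1] else dims,
    scale_assignment = list(fine = idx[["1"]] %||% integer(0),
                            mid = idx[["2"]] %||% integer(0),
                            coarse = idx[["3"]] %||% integer(0)),
    mean_best_iou = mean_best_iou
  ), class = "anchor_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

anchor_dims_matrix <- function(anchors) {
  check_dims(anchors$dims, anchors$shape)
}

#' @export
print.anchor_set <- function(x, ...) {
  k <- if (x$shape == "circle") length(x$dims) else nrow(x$dims)
  cat("Anchor set:", k, x$shape, "anchors\n")
  if (x$shape == "circle") {
    cat("  radii:", paste(signif(x$dims, 4), collapse = ", "), "\n")
  } else {
    cat("  (w, h):", paste(apply(signif(x$dims, 4), 1, paste, collapse = "x"),
                           collapse = ", "), "\n")
  }
  if (!is.null(x$mean_best_iou))
    cat("  mean best IoU:", signif(x$mean_best_iou, 4), "\n")
  invisible(x)
}

# Distance of every row of dims to every center; n x k matrix.
dist_to_centers <- function(dims, centers, shape) {
  n <- nrow(dims); k <- nrow(centers)
  out <- matrix(0, n, k)
  for (j in seq_len(k)) {
    out[, j] <- 1 - concentric_iou(
      if (shape == "circle") dims[, 1] else dims,
      if (shape == "circle") centers[j, 1] else centers[j, , drop = FALSE],
      shape)
  }
  out
}

kmeans_pp_init <- function(dims, k, shape) {
  n <- nrow(dims)
  centers <- matrix(NA_real_, k, ncol(dims))
  centers[1, ] <- dims[sample.int(n, 1L), ]
  if (k > 1L) {
    d2 <- dist_to_centers(dims, centers[1, , drop = FALSE], shape)[, 1]^2
    for (j in 2:k) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j, ] <- dims[sample.int(n, 1L, prob = p), ]
      dj <- dist_to_centers(dims, centers[j, , drop = FALSE], shape)[, 1]^2
      d2 <- pmin(d2, dj)
    }
  }
  centers
}

#' Cluster ground-truth box dimensions into prior anchors
#'
#' Lloyd-style k-means over box dimensions under the IoU distance
#' ([iou_distance()]), the standard recipe for deriving detector anchor
#' priors from a training set. Points are assigned to the nearest center by
#' IoU distance, centers are updated as the arithmetic mean of their
#' members' dimensions, and iteration stops when the assignment stabilizes
#' (or after `max_iter` sweeps). Initialization is k-means++-style seeding
#' under the same distance; clusters that empty out are re-seeded from the
#' point farthest from its nearest center. The best of `n_restarts` runs by
#' mean best IoU is returned.
#'
#' @param gt_dims Ground-truth dimensions: radii for circles, 2-column
#'   `(w, h)` matrix for rects.
#' @param k Number of anchors (default 9, split three per detection scale).
#' @param shape `"circle"` or `"rect"`.
#' @param seed Integer seed; the run is deterministic given
#'   `(seed, n_restarts)`.
#' @param n_restarts Independent restarts (default 10).
#' @param max_iter Maximum Lloyd sweeps per restart (default 300).
#' @return An [anchor_set()] whose `mean_best_iou` element holds the mean
#'   over ground truths of the best concentric IoU to any anchor.
#' @examples
#' radii <- c(rnorm(50, 10, 0.2), rnorm(50, 30, 0.5))
#' kmeans_anchors(radii, k = 2, shape = "circle", seed = 1)
#' @export
kmeans_anchors <- function(gt_dims, k = 9, shape = c("circle", "rect"),
                           seed = 0, n_restarts = 10, max_iter = 300) {
  shape <- match.arg(shape)
  dims <- check_dims(gt_dims, shape)
  n <- nrow(dims)
  if (k < 1) stop_input("k must be at least 1")
  if (k > n) stop_input("k exceeds the number of ground-truth boxes")

  best <- NULL
  for (rs in seq_len(n_restarts)) {
    res <- with_seed(child_seed(seed, rs), {
      centers <- kmeans_pp_init(dims, k, shape)
      assign_prev <- rep(0L, n)
      for (it in seq_len(max_iter)) {
        d <- dist_to_centers(dims, centers, shape)
        assign_cur <- max.col(-d, ties.method = "first")
        empty <- setdiff(seq_len(k), unique(assign_cur))
        if (length(empty)) {
          dmin <- d[cbind(seq_len(n), assign_cur)]
          for (j in empty) {
            far <- which.max(dmin)
            centers[j, ] <- dims[far, ]
            dmin[far] <- 0
          }
          d <- dist_to_centers(dims, centers, shape)
          assign_cur <- max.col(-d, ties.method = "first")
        }
        if (identical(assign_cur, assign_prev)) break
        assign_prev <- assign_cur
        for (j in seq_len(k)) {
          member <- assign_cur == j
          if (any(member)) centers[j, ] <- colMeans(dims[member, , drop = FALSE])
        }
      }
      centers
    })
    mbi <- mean_best_concentric_iou(dims, res, shape)
    if (is.null(best) || mbi > best$mbi) best <- list(centers = res, mbi = mbi)
  }
  anchor_set(if (shape == "circle") best$centers[, 1] else best$centers,
             shape, mean_best_iou = best$mbi)
}

mean_best_concentric_iou <- function(dims, centers, shape) {
  d <- dist_to_centers(dims, centers, shape)
  mean(1 - apply(d, 1, min))
}

#' Average best IoU between ground truths and an anchor set
#'
#' The anchor-quality diagnostic used to choose the number of clusters and
#' to compare circular against rectangular anchors: the mean, over ground
#' truths, of the maximum concentric IoU to any anchor. Higher values mean
#' the priors are easier to regress from.
#'
#' @param gt_dims Ground-truth dimensions (radii or `(w, h)` matrix).
#' @param anchors An [anchor_set()].
#' @return A single value in `[0, 1]`.
#' @export
average_best_iou <- function(gt_dims, anchors) {
  if (!inherits(anchors, "anchor_set")) stop_input("anchors must be an anchor_set")
  dims <- check_dims(gt_dims, anchors$shape)
  if (nrow(dims) == 0L) stop_input("empty ground-truth dimension list")
  mean_best_concentric_iou(dims, anchor_dims_matrix(anchors), anchors$shape)
}

#' Write or read an anchor configuration file
#'
#' Anchor sets are exchanged between the clustering step and the decoding /
#' loss machinery as a small YAML file holding the shape, the sorted
#' dimensions and the scale partition.
#'
#' @param anchors An [anchor_set()].
#' @param path File path.
#' @return `write_anchor_config` returns `path` invisibly;
#'   `read_anchor_config` returns an [anchor_set()].
#' @export
write_anchor_config <- function(anchors, path) {
  if (!inherits(anchors, "anchor_set")) stop_input("anchors must be an anchor_set")
  dims <- anchor_dims_matrix(anchors)
  obj <- list(
    shape = anchors$shape,
    dims = if (anchors$shape == "circle") as.numeric(dims) else
      lapply(seq_len(nrow(dims)), function(i) as.numeric(dims[i, ])),
    mean_best_iou = anchors$mean_best_iou
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_anchor_config
#' @export
read_anchor_config <- function(path) {
  obj <- yaml::read_yaml(path)
  dims <- if (obj$shape == "circle") as.numeric(obj$dims) else
    do.call(rbind, lapply(obj$dims, as.numeric))
  anchor_set(dims, obj$shape, mean_best_iou = obj$mean_best_iou)
}
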