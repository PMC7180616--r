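# Independent reference implementations used to check the package against.
# These deliberately take the dumbest correct route (sampling, counting,
# exhaustive enumeration) rather than sharing code paths with the package.

# Monte-Carlo estimate of the overlap area of two circles: uniform samples
# over the bounding square of the pair. Returns the estimate and its
# standard error.
mc_circle_overlap <- function(a, b, n = 1e6) {
  xmin <- min(a$cx - a$r, b$cx - b$r); xmax <- max(a$cx + a$r, b$cx + b$r)
  ymin <- min(a$cy - a$r, b$cy - b$r); ymax <- max(a$cy + a$r, b$cy + b$r)
  side <- max(xmax - xmin, ymax - ymin)
  x <- runif(n, xmin, xmin + side)
  y <- runif(n, ymin, ymin + side)
  inside <- ((x - a$cx)^2 + (y - a$cy)^2 <= a$r^2) &
            ((x - b$cx)^2 + (y - b$cy)^2 <= b$r^2)
  p <- mean(inside)
  list(est = p * side^2, se = side^2 * sqrt(p * (1 - p) / n))
}

# Rasterized IoU of two integer-aligned rectangles by counting unit cells.
raster_rect_iou <- function(a, b) {
  cells <- function(rc) {
    xs <- seq(rc$cx - rc$w / 2 + 0.5, by = 1, length.out = rc$w)
    ys <- seq(rc$cy - rc$h / 2 + 0.5, by = 1, length.out = rc$h)
    if (!rc$w || !rc$h) return(character(0))
    as.vector(outer(xs, ys, paste))
  }
  ca <- cells(a); cb <- cells(b)
  inter <- length(intersect(ca, cb))
  un <- length(union(ca, cb))
  if (un == 0) 0 else inter / un
}

# Brute-force greedy NMS: full O(n^2) pairwise IoU table up front, then a
# repeated argmax scan over a shrinking index set, ties to the lowest
# original index.
brute_nms <- function(det, lambda, shape = "circle") {
  n <- nrow(det)
  a <- det[rep(seq_len(n), each = n), , drop = FALSE]
  b <- det[rep(seq_len(n), times = n), , drop = FALSE]
  v <- if (shape == "circle") circle_iou(a, b) else rect_iou(a, b)
  pair_iou <- matrix(v, n, n, byrow = TRUE)   # [i, j] = IoU(det i, det j)
  remaining <- seq_len(n)
  kept <- integer(0)
  while (length(remaining)) {
    conf <- det$confidence[remaining]
    m <- remaining[which(conf == max(conf))[1]]
    kept <- c(kept, m)
    remaining <- setdiff(remaining, m)
    remaining <- remaining[pair_iou[m, remaining] < lambda]
  }
  kept
}

# Average precision by exhaustive threshold enumeration: re-match, sweep
# every distinct confidence, build the envelope point by point.
ap_enumeration <- function(dets, gts, iou_thresh = 0.5, shape = "circle") {
  n_det <- nrow(dets); n_gt <- nrow(gts)
  ord <- order(-dets$confidence, seq_len(n_det))
  matched <- rep(FALSE, n_gt)
  is_tp <- logical(n_det)
  for (i in ord) {
    best <- -1; bj <- 0L
    for (j in seq_len(n_gt)) {
      if (matched[j]) next
      iou <- if (shape == "circle") {
        circle_iou(dets[i, , drop = FALSE], gts[j, , drop = FALSE])
      } else {
        rect_iou(dets[i, , drop = FALSE], gts[j, , drop = FALSE])
      }
      if (iou > best) { best <- iou; bj <- j }
    }
    if (bj > 0L && best >= iou_thresh) { matched[bj] <- TRUE; is_tp[i] <- TRUE }
  }
  th <- sort(unique(dets$confidence), decreasing = TRUE)
  rs <- ps <- numeric(length(th))
  for (k in seq_along(th)) {
    sel <- dets$confidence >= th[k]
    tp <- sum(is_tp & sel); fp <- sum(sel) - tp
    rs[k] <- tp / n_gt
    ps[k] <- if (tp + fp > 0) tp / (tp + fp) else 0
  }
  ap <- 0; prev_r <- 0
  for (k in seq_along(rs)) {
    p_interp <- max(ps[rs >= rs[k]])
    ap <- ap + (rs[k] - prev_r) * p_interp
    prev_r <- rs[k]
  }
  ap
}

# Random circle pair spanning the disjoint / lens / containment regimes.
random_circle_pair <- function() {
  R <- runif(1, 0.5, 40)
  r <- runif(1, 0.5, 40)
  regime <- sample(c("disjoint", "lens", "containment"), 1)
  d <- switch(regime,
    disjoint = runif(1, 1, 1.8) * (R + r),
    lens = runif(1, abs(R - r) + 1e-3, R + r - 1e-3),
    containment = runif(1, 0, max(abs(R - r) - 1e-3, 0)))
  ang <- runif(1, 0, 2 * pi)
  cx <- runif(1, -20, 20); cy <- runif(1, -20, 20)
  list(a = circle_box(cx, cy, R),
       b = circle_box(cx + d * cos(ang), cy + d * sin(ang), r),
       regime = regime, d = d)
}

# Random circular detection table for NMS / metrics property tests.
random_detections <- function(n, extent = 100, rmin = 3, rmax = 20) {
  d <- circle_box(runif(n, 0, extent), runif(n, 0, extent),
                  runif(n, rmin, rmax))
  d$confidence <- round(runif(n), 3)  # rounding plants occasional ties
  d
}
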