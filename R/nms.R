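# Box-shape detection shared by nms and metrics: a detection table is
# circular if it has an `r` column, rectangular if it has `w` and `h`.
detect_shape <- function(x, shape = NULL) {
  has_c <- all(c("cx", "cy", "r") %in% names(x))
  has_r <- all(c("cx", "cy", "w", "h") %in% names(x))
  if (!is.null(shape)) {
    shape <- match.arg(shape, c("circle", "rect"))
    if (shape == "circle" && !has_c) stop_input("no circle columns (cx, cy, r)")
    if (shape == "rect" && !has_r) stop_input("no rectangle columns (cx, cy, w, h)")
    return(shape)
  }
  if (has_c && has_r)
    stop_input("both circle and rectangle columns present; pass `shape`")
  if (has_c) return("circle")
  if (has_r) return("rect")
  stop_input("detections need circle (cx, cy, r) or rectangle (cx, cy, w, h) columns")
}

box_iou <- function(a, b, shape) {
  if (shape == "circle") circle_iou(a, b) else rect_iou(a, b)
}

#' Greedy non-maximum suppression
#'
#' Removes redundant detections of the same object: repeatedly select the
#' remaining detection with the highest confidence, keep it, and delete all
#' remaining detections whose IoU with it is at least `lambda`. With
#' circular boxes the IoU is the exact circle-circle IoU ([circle_iou()]),
#' which matches round fruit more tightly than the rectangle IoU and so
#' discriminates better between a duplicate detection and a genuinely
#' adjacent fruit.
#'
#' Ties in confidence are broken toward the earlier input row, giving a
#' total order; the kept set is then invariant to permutations of the
#' input. Suppression uses `>= lambda` (not `>`).
#'
#' @param detections Data frame with box columns (`cx`, `cy`, `r` for
#'   circles or `cx`, `cy`, `w`, `h` for rectangles) and a `confidence`
#'   column in `[0, 1]`.
#' @param lambda Suppression threshold in `[0, 1]`. The default 0.5 is the
#'   community convention.
#' @param shape `"circle"` or `"rect"`; inferred from the columns when
#'   unambiguous.
#' @param per_class If `TRUE` and a `class_id` column exists, suppression is
#'   applied independently within each class. Default `FALSE`
#'   (class-agnostic, appropriate for a single-class task).
#' @return The kept rows, in selection order (non-increasing confidence),
#'   with an integer attribute `"kept"` giving their original row indices.
#' @examples
#' d <- circle_box(c(0, 1, 30), 0, 10)
#' d$confidence <- c(0.9, 0.8, 0.7)
#' nms(d, lambda = 0.5)
#' @export
nms <- function(detections, lambda = 0.5, shape = NULL, per_class = FALSE) {
  if (!is.data.frame(detections)) stop_input("detections must be a data frame")
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1)
    stop_input("lambda must be a single number in [0, 1]")
  if (nrow(detections) == 0L) {
    out <- detections
    attr(out, "kept") <- integer(0)
    return(out)
  }
  if (!"confidence" %in% names(detections))
    stop_input("detections need a confidence column")
  conf <- detections$confidence
  if (any(!is.finite(conf)) || any(conf < 0) || any(conf > 1))
    stop_input("confidence values must lie in [0, 1]")
  shape <- detect_shape(detections, shape)

  if (isTRUE(per_class) && "class_id" %in% names(detections)) {
    idx <- seq_len(nrow(detections))
    kept <- unlist(lapply(split(idx, detections$class_id), function(ii) {
      sub <- nms(detections[ii, , drop = FALSE], lambda, shape, per_class = FALSE)
      ii[attr(sub, "kept")]
    }), use.names = FALSE)
    kept <- kept[order(-conf[kept], kept)]
    out <- detections[kept, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "kept") <- kept
    return(out)
  }

  # validate box columns once, then work on plain vectors
  cx <- detections$cx; cy <- detections$cy
  if (shape == "circle") {
    circle_box(cx, cy, detections$r)
    rr <- detections$r
  } else {
    rect_box(cx, cy, detections$w, detections$h)
    ww <- detections$w; hh <- detections$h
  }
  iou_to <- function(i, cand) {
    if (shape == "circle") {
      circle_iou_num(cx[i], cy[i], rr[i], cx[cand], cy[cand], rr[cand])
    } else {
      rect_iou_num(cx[i], cy[i], ww[i], hh[i],
                   cx[cand], cy[cand], ww[cand], hh[cand])
    }
  }
  ord <- order(-conf, seq_along(conf))  # stable: ties -> earlier input row
  alive <- rep(TRUE, length(conf))
  kept <- integer(0)
  for (i in ord) {
    if (!alive[i]) next
    kept <- c(kept, i)
    alive[i] <- FALSE
    cand <- which(alive)
    if (length(cand)) {
      alive[cand[iou_to(i, cand) >= lambda]] <- FALSE
    }
  }
  out <- detections[kept, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "kept") <- kept
  out
}
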