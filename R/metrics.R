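#' Match detections against ground truths
#'
#' Greedy matching in the usual benchmark convention: detections are
#' processed in non-increasing confidence order (ties toward the earlier
#' row); each detection claims its best-IoU still-unmatched ground truth
#' and is a true positive if that IoU reaches `iou_thresh`, otherwise a
#' false positive. Ground truths left unclaimed are false negatives.
#'
#' @param dets Detection data frame (box columns plus `confidence`).
#' @param gts Ground-truth data frame with the same box geometry.
#' @param iou_thresh Matching IoU threshold (default 0.5).
#' @param shape `"circle"` or `"rect"`; inferred when unambiguous.
#' @return A list of class `match_result`: `det_label` (character
#'   `"TP"`/`"FP"` per detection, input order), `gt_matched` (logical per
#'   ground truth), and counts `tp`, `fp`, `fn`.
#' @export
match_detections <- function(dets, gts, iou_thresh = 0.5, shape = NULL) {
  n_det <- nrow(dets); n_gt <- nrow(gts)
  if (n_det > 0 && n_gt > 0) {
    shape <- detect_shape(dets, shape)
    detect_shape(gts, shape)  # enforce same geometry
  } else if (n_det > 0) {
    shape <- detect_shape(dets, shape)
  }
  label <- character(n_det)
  matched <- rep(FALSE, n_gt)
  if (n_det > 0) {
    dx <- dets$cx; dy <- dets$cy
    gx <- gts$cx; gy <- gts$cy
    if (!is.null(shape) && shape == "rect") {
      dw <- dets$w; dh <- dets$h; gw <- gts$w; gh <- gts$h
      iou_to <- function(i, free)
        rect_iou_num(dx[i], dy[i], dw[i], dh[i], gx[free], gy[free],
                     gw[free], gh[free])
    } else {
      dr <- dets$r; gr <- gts$r
      iou_to <- function(i, free)
        circle_iou_num(dx[i], dy[i], dr[i], gx[free], gy[free], gr[free])
    }
    ord <- order(-dets$confidence, seq_len(n_det))
    for (i in ord) {
      if (!any(!matched)) { label[i] <- "FP"; next }
      free <- which(!matched)
      iou <- iou_to(i, free)
      j <- which.max(iou)
      if (iou[j] >= iou_thresh) {
        label[i] <- "TP"
        matched[free[j]] <- TRUE
      } else {
        label[i] <- "FP"
      }
    }
  }
  structure(list(det_label = label, gt_matched = matched,
                 tp = sum(label == "TP"), fp = sum(label == "FP"),
                 fn = sum(!matched)),
            class = "match_result")
}

#' Recall, precision and F1 at a confidence threshold
#'
#' Filters detections at `conf_thresh`, matches against ground truth and
#' reports `Recall = TP / (TP + FN)`, `Precision = TP / (TP + FP)` and
#' `F1 = 2 R P / (R + P)` (0 when `R + P = 0`). With no detections above
#' the threshold the precision is undefined; it is reported as 0 with
#' `precision_defined = FALSE`.
#'
#' @inheritParams match_detections
#' @param conf_thresh Confidence threshold (default 0.8, a common operating
#'   point for reporting a single recall/precision pair).
#' @return A list with `recall`, `precision`, `f1`, `tp`, `fp`, `fn`,
#'   `precision_defined`.
#' @export
prf_at_threshold <- function(dets, gts, conf_thresh = 0.8, iou_thresh = 0.5,
                             shape = NULL) {
  if (nrow(gts) == 0L)
    stop_input("no ground truths: recall is undefined")
  keep <- dets[dets$confidence >= conf_thresh, , drop = FALSE]
  m <- match_detections(keep, gts, iou_thresh, shape)
  recall <- m$tp / (m$tp + m$fn)
  pdef <- (m$tp + m$fp) > 0
  precision <- if (pdef) m$tp / (m$tp + m$fp) else 0
  f1 <- if (recall + precision > 0) 2 * recall * precision / (recall + precision) else 0
  list(recall = recall, precision = precision, f1 = f1,
       tp = m$tp, fp = m$fp, fn = m$fn, precision_defined = pdef)
}

#' Precision-recall curve from a confidence sweep
#'
#' Matches all detections once (greedy, confidence order) and sweeps the
#' confidence threshold through every distinct confidence value, yielding
#' one (recall, precision) point per threshold in decreasing-confidence
#' order (detections tied in confidence enter together), plus the
#' interpolated precision envelope
#' `p_interp(r) = max over recalls >= r of measured precision`.
#'
#' @inheritParams match_detections
#' @return A data frame of class `pr_curve` with columns `confidence`,
#'   `recall`, `precision`, `p_interp`, ordered by decreasing confidence;
#'   attribute `"n_gt"` records the ground-truth count.
#' @export
pr_curve <- function(dets, gts, iou_thresh = 0.5, shape = NULL) {
  if (nrow(gts) == 0L) stop_input("no ground truths: recall is undefined")
  m <- match_detections(dets, gts, iou_thresh, shape)
  ord <- order(-dets$confidence, seq_len(nrow(dets)))
  lab <- m$det_label[ord]
  tp <- cumsum(lab == "TP"); fp <- cumsum(lab == "FP")
  recall <- tp / nrow(gts)
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  conf <- dets$confidence[ord]
  last_of_tie <- c(conf[-length(conf)] != conf[-1], TRUE)
  out <- data.frame(confidence = conf, recall = recall,
                    precision = precision)[last_of_tie, , drop = FALSE]
  rownames(out) <- NULL
  out$p_interp <- rev(cummax(rev(out$precision)))
  attr(out, "n_gt") <- nrow(gts)
  class(out) <- c("pr_curve", class(out))
  out
}

#' Interpolated average precision
#'
#' Area under the interpolated precision-recall envelope, using all-point
#' interpolation: `AP = sum_n (r_{n+1} - r_n) * p_interp(r_{n+1})` with
#' `p_interp(r) = max over recalls >= r of measured precision` and
#' `r_0 = 0`.
#'
#' @param curve A [pr_curve()] (or any data frame with `recall` and
#'   `precision` columns ordered by decreasing confidence).
#' @return AP in `[0, 1]`; an empty curve yields 0 with a warning.
#' @export
average_precision <- function(curve) {
  if (is.null(curve) || nrow(curve) == 0L) {
    warning("empty precision-recall curve; AP = 0", call. = FALSE)
    return(0)
  }
  p_interp <- rev(cummax(rev(curve$precision)))
  dr <- diff(c(0, curve$recall))
  sum(dr * p_interp)
}

#' Average precision over random image sub-datasets
#'
#' Repeatedly samples subsets of images and computes the AP over each,
#' giving a per-subset AP distribution suitable for paired detector
#' comparison. Images are sampled without replacement within a subset and
#' independently across subsets; the sequence is deterministic given
#' `seed`.
#'
#' @param dets,gts Data frames with an `image_id` column in addition to
#'   box/confidence columns.
#' @param n_subsets Number of sub-datasets (default 30).
#' @param subset_size Images per sub-dataset (default 80).
#' @param seed Integer seed.
#' @inheritParams match_detections
#' @return Numeric vector of `n_subsets` AP values.
#' @export
subsample_ap <- function(dets, gts, n_subsets = 30, subset_size = 80,
                         seed = 0, iou_thresh = 0.5, shape = NULL) {
  if (!"image_id" %in% names(gts) || !"image_id" %in% names(dets))
    stop_input("dets and gts need an image_id column")
  images <- sort(unique(c(as.character(gts$image_id), as.character(dets$image_id))))
  if (length(images) < subset_size)
    stop_input("fewer images (", length(images), ") than subset_size (", subset_size, ")")
  with_seed(seed, {
    vapply(seq_len(n_subsets), function(i) {
      pick <- sample(images, subset_size)
      d <- dets[dets$image_id %in% pick, , drop = FALSE]
      g <- gts[gts$image_id %in% pick, , drop = FALSE]
      if (nrow(g) == 0L) return(NA_real_)
      average_precision(pr_curve(d, g, iou_thresh, shape))
    }, 0)
  })
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test for paired per-subset scores (e.g. the AP of
#' two detectors over the same sub-datasets). Zero differences are dropped,
#' tied absolute differences receive mid-ranks, the null distribution is
#' enumerated exactly for up to 12 effective pairs and approximated by a
#' continuity-corrected normal (with tie-corrected variance) beyond that.
#' Decisions are conventionally reported at a significance level of 0.05.
#'
#' @param ap_a,ap_b Paired score vectors of equal length.
#' @param method `"auto"` (exact up to 12 effective pairs, normal beyond),
#'   or force `"exact"` / `"normal"`.
#' @return A list with `statistic` (rank sum of positive differences `W`),
#'   `p_value`, `n_effective`, `method` (`"exact"` or `"normal"`), and
#'   `degenerate` (`TRUE` when all differences are zero, in which case
#'   `p_value = 1`).
#' @examples
#' wilcoxon_signed_rank(c(5, 6, 7, 8, 9, 10), c(1, 2, 3, 4, 5, 6))$p_value
#' # 0.03125
#' @export
wilcoxon_signed_rank <- function(ap_a, ap_b,
                                 method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  if (length(ap_a) != length(ap_b))
    stop_input("paired vectors must have equal length")
  d <- ap_a - ap_b
  d <- d[!is.na(d)]
  nz <- d != 0
  if (!any(nz)) {
    return(list(statistic = 0, p_value = 1, n_effective = 0L,
                method = "degenerate", degenerate = TRUE))
  }
  d <- d[nz]
  n <- length(d)
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  use_exact <- switch(method, auto = n <= 12L, exact = TRUE, normal = FALSE)
  if (use_exact) {
    # Exact enumeration of all 2^n sign assignments under the null.
    total <- 2^n
    sums <- numeric(total)
    for (m in 0:(total - 1)) {
      bits <- bitwAnd(m, bitwShiftL(1L, 0:(n - 1L))) != 0L
      sums[m + 1] <- sum(rk[bits])
    }
    p_le <- mean(sums <= W)
    p_ge <- mean(sums >= W)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(rk)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - 0.5 * sign(W - mu)) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(statistic = W, p_value = p, n_effective = n, method = method,
       degenerate = FALSE)
}
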