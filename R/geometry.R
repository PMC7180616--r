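#' Construct circular bounding boxes
#'
#' A circular bounding box (C-Bbox) localizes a round object by its center
#' and radius, in continuous pixel coordinates with the origin at the image
#' top-left corner, x rightward and y downward. Circles are stored as plain
#' data frames with columns `cx`, `cy`, `r`, one row per box.
#'
#' @param cx,cy Center coordinates in pixels.
#' @param r Radius in pixels; must be non-negative.
#' @return A data frame with columns `cx`, `cy`, `r`.
#' @seealso [rect_box()], [circle_iou()]
#' @examples
#' circle_box(100, 120, 30)
#' @export
circle_box <- function(cx, cy, r) {
  cx <- as.numeric(cx); cy <- as.numeric(cy); r <- as.numeric(r)
  if (any(!is.finite(cx)) || any(!is.finite(cy)) || any(!is.finite(r)))
    stop_input("circle coordinates and radii must be finite")
  if (any(r < 0)) stop_input("circle radius must be non-negative")
  data.frame(cx = cx, cy = cy, r = r)
}

#' Construct rectangular bounding boxes (center format)
#'
#' The conventional axis-aligned rectangular box (R-Bbox), stored in center
#' format as a data frame with columns `cx`, `cy`, `w`, `h`.
#'
#' @param cx,cy Center coordinates in pixels.
#' @param w,h Width and height in pixels; must be non-negative.
#' @return A data frame with columns `cx`, `cy`, `w`, `h`.
#' @export
rect_box <- function(cx, cy, w, h) {
  cx <- as.numeric(cx); cy <- as.numeric(cy)
  w <- as.numeric(w); h <- as.numeric(h)
  if (any(!is.finite(c(cx, cy, w, h))))
    stop_input("rectangle coordinates and sizes must be finite")
  if (any(w < 0) || any(h < 0)) stop_input("rectangle sizes must be non-negative")
  data.frame(cx = cx, cy = cy, w = w, h = h)
}

as_circle_df <- function(x) {
  if (!is.data.frame(x) || !all(c("cx", "cy", "r") %in% names(x)))
    stop_input("expected a data frame with columns cx, cy, r")
  circle_box(x$cx, x$cy, x$r)
}

as_rect_df <- function(x) {
  if (!is.data.frame(x) || !all(c("cx", "cy", "w", "h") %in% names(x)))
    stop_input("expected a data frame with columns cx, cy, w, h")
  rect_box(x$cx, x$cy, x$w, x$h)
}

# Numeric workers shared with the suppression/matching hot paths; inputs
# are plain vectors, already validated.
circle_overlap_area_num <- function(ax, ay, aR, bx, by, br) {
  n <- max(length(ax), length(bx))
  ax <- rep_len(ax, n); ay <- rep_len(ay, n); aR <- rep_len(aR, n)
  bx <- rep_len(bx, n); by <- rep_len(by, n); br <- rep_len(br, n)
  d <- sqrt((ax - bx)^2 + (ay - by)^2)
  big <- pmax(aR, br); small <- pmin(aR, br)
  area <- numeric(length(d))
  disjoint <- d >= aR + br
  contained <- !disjoint & d <= big - small
  lens <- !disjoint & !contained
  area[contained] <- pi * small[contained]^2
  if (any(lens)) {
    Rl <- aR[lens]; rl <- br[lens]; dl <- d[lens]
    th <- acos(clamp((Rl^2 + dl^2 - rl^2) / (2 * Rl * dl), -1, 1))
    ph <- acos(clamp((rl^2 + dl^2 - Rl^2) / (2 * rl * dl), -1, 1))
    area[lens] <- th * Rl^2 + ph * rl^2 -
      0.5 * Rl^2 * sin(2 * th) - 0.5 * rl^2 * sin(2 * ph)
  }
  pmax(area, 0)
}

circle_iou_num <- function(ax, ay, aR, bx, by, br) {
  ov <- circle_overlap_area_num(ax, ay, aR, bx, by, br)
  un <- pi * aR^2 + pi * br^2 - ov
  ifelse(un > 0, pmin(ov / un, 1), 0)
}

rect_iou_num <- function(ax, ay, aw, ah, bx, by, bw, bh) {
  iw <- pmax(0, pmin(ax + aw / 2, bx + bw / 2) - pmax(ax - aw / 2, bx - bw / 2))
  ih <- pmax(0, pmin(ay + ah / 2, by + bh / 2) - pmax(ay - ah / 2, by - bh / 2))
  inter <- iw * ih
  un <- aw * ah + bw * bh - inter
  ifelse(un > 0, pmin(inter / un, 1), 0)
}

#' Exact overlap area of two circles
#'
#' Computes the intersection (lens) area of two circles in closed form. With
#' radii `R`, `r` and center distance `d`, three regimes apply:
#' * `d >= R + r`: the circles are disjoint (or externally tangent), area 0;
#' * `d <= |R - r|`: one circle contains the other, area `pi * min(R, r)^2`;
#' * otherwise the lens area
#'   `theta*R^2 + phi*r^2 - R^2*sin(2*theta)/2 - r^2*sin(2*phi)/2` with
#'   `theta = acos((R^2 + d^2 - r^2) / (2*R*d))` and
#'   `phi = acos((r^2 + d^2 - R^2) / (2*r*d))`.
#'
#' The `acos` arguments are clamped to `[-1, 1]`: near internal or external
#' tangency, floating-point drift can push them marginally outside the
#' mathematical range, and clamping makes the formula continuous across the
#' regime boundaries.
#'
#' @param a,b Circle data frames (see [circle_box()]); rows are recycled
#'   when one argument has a single row.
#' @return Numeric vector of overlap areas in squared pixels.
#' @examples
#' circle_overlap_area(circle_box(0, 0, 1), circle_box(1, 0, 1))
#' # 2*pi/3 - sqrt(3)/2
#' @export
circle_overlap_area <- function(a, b) {
  a <- as_circle_df(a); b <- as_circle_df(b)
  ab <- recycle_rows(a, b); a <- ab$a; b <- ab$b
  circle_overlap_area_num(a$cx, a$cy, a$r, b$cx, b$cy, b$r)
}

#' Intersection-over-union of two circles
#'
#' `IoU = A_overlap / (pi*R^2 + pi*r^2 - A_overlap)` with the overlap area
#' from [circle_overlap_area()]. In the containment regime this reduces to
#' `(min(R, r) / max(R, r))^2`. Degenerate pairs whose union area is zero
#' (both radii zero) are defined to have IoU 0, which keeps suppression and
#' matching total functions.
#'
#' @inheritParams circle_overlap_area
#' @return Numeric vector of IoU values in `[0, 1]`; symmetric in `a`, `b`.
#' @export
circle_iou <- function(a, b) {
  a <- as_circle_df(a); b <- as_circle_df(b)
  ab <- recycle_rows(a, b); a <- ab$a; b <- ab$b
  circle_iou_num(a$cx, a$cy, a$r, b$cx, b$cy, b$r)
}

#' Intersection-over-union of two axis-aligned rectangles
#'
#' Standard rectangle IoU in center format; the baseline the circular IoU is
#' compared against. Pairs whose union area is zero are assigned IoU 0.
#'
#' @param a,b Rectangle data frames (see [rect_box()]); rows recycled as in
#'   [circle_overlap_area()].
#' @return Numeric vector of IoU values in `[0, 1]`.
#' @export
rect_iou <- function(a, b) {
  a <- as_rect_df(a); b <- as_rect_df(b)
  ab <- recycle_rows(a, b); a <- ab$a; b <- ab$b
  rect_iou_num(a$cx, a$cy, a$w, a$h, b$cx, b$cy, b$w, b$h)
}

#' Convert rectangles to circles
#'
#' Derives a circular box from a rectangular annotation, preserving the
#' center. How circular ground truth is best obtained from rectangular
#' annotations is a convention choice, so several radius rules are offered:
#' `"mean"` (default) uses `(w + h) / 4`, `"min"` and `"max"` use the half
#' side lengths, `"circumscribed"` uses the half diagonal.
#'
#' @param rect Rectangle data frame (see [rect_box()]).
#' @param mode Radius rule; one of `"mean"`, `"min"`, `"max"`,
#'   `"circumscribed"`.
#' @return A circle data frame with the same number of rows.
#' @export
rect_to_circle <- function(rect, mode = c("mean", "min", "max", "circumscribed")) {
  rect <- as_rect_df(rect)
  mode <- match.arg(mode)
  r <- switch(mode,
    mean = (rect$w + rect$h) / 4,
    min = pmin(rect$w, rect$h) / 2,
    max = pmax(rect$w, rect$h) / 2,
    circumscribed = sqrt(rect$w^2 + rect$h^2) / 2
  )
  circle_box(rect$cx, rect$cy, r)
}

#' Convert circles to their tight enclosing squares
#'
#' @param circle Circle data frame (see [circle_box()]).
#' @return A rectangle data frame with `w = h = 2 * r` and the same centers.
#' @export
circle_to_rect <- function(circle) {
  circle <- as_circle_df(circle)
  rect_box(circle$cx, circle$cy, 2 * circle$r, 2 * circle$r)
}
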