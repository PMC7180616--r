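#' Raw detection head output container
#'
#' Holds the raw (pre-activation) network outputs for one detection scale:
#' an `S x S` grid with `B` anchors per cell, each slot carrying three
#' coordinates `t_x`, `t_y`, `t_r`, a raw confidence `t_conf` and
#' `n_classes` raw class scores. A circular box needs only three
#' coordinates per slot (center offsets and a log-radius), one fewer than
#' the four of a rectangular box. Arrays are indexed
#' `[cell_y + 1, cell_x + 1, anchor]` with cells counted from the image
#' top-left corner.
#'
#' @param grid_size Cells per side `S`.
#' @param anchors_per_cell Anchors per cell `B`.
#' @param n_classes Number of classes (default 1).
#' @param stride Pixels per cell at this scale.
#' @param fill Initial value for all raw outputs (default 0).
#' @return An object of class `head_output`.
#' @export
head_output <- function(grid_size, anchors_per_cell, n_classes = 1,
                        stride, fill = 0) {
  S <- as.integer(grid_size); B <- as.integer(anchors_per_cell)
  C <- as.integer(n_classes)
  if (S < 1 || B < 1 || C < 1) stop_input("grid_size, anchors_per_cell, n_classes must be >= 1")
  structure(list(
    S = S, B = B, C = C, stride = stride,
    t_x = array(fill, c(S, S, B)),
    t_y = array(fill, c(S, S, B)),
    t_r = array(fill, c(S, S, B)),
    t_conf = array(fill, c(S, S, B)),
    t_class = array(fill, c(S, S, B, C))
  ), class = "head_output")
}

check_head <- function(head) {
  if (!inherits(head, "head_output")) stop_input("expected a head_output object")
  vals <- c(head$t_x, head$t_y, head$t_r, head$t_conf, head$t_class)
  if (any(is.na(vals)) || any(!is.finite(vals)))
    stop_input("head output contains non-finite values")
  invisible(head)
}

# Cell-offset arrays in grid units, matching the [S, S, B] layout.
cell_offsets <- function(S, B) {
  list(cx = array(rep(0:(S - 1), each = S), c(S, S, B)),
       cy = array(rep(0:(S - 1), times = S), c(S, S, B)))
}

#' Decode raw head output into circular detections
#'
#' Applies the grid-cell parameterization: for a cell with offset
#' `(c_x, c_y)` from the image top-left and a prior anchor radius `p_r`,
#' `x_hat = sigmoid(t_x) + c_x`, `y_hat = sigmoid(t_y) + c_y` (grid units,
#' then scaled by the stride to pixels) and `r_hat = p_r * exp(t_r)`
#' (pixels). Confidence and class scores pass through a sigmoid.
#'
#' @param head A [head_output()].
#' @param anchor_radii Prior radii (pixels) for this scale; length must
#'   equal `head$B`.
#' @param conf_thresh Drop decoded detections below this confidence
#'   (default 0, keep everything).
#' @return Data frame of circular detections with columns `cx`, `cy`, `r`
#'   (pixels), `confidence`, `class_id`, per-class probability columns
#'   `p1..pC`, and slot bookkeeping columns `cell_x`, `cell_y`, `anchor`.
#' @export
decode_head <- function(head, anchor_radii, conf_thresh = 0) {
  check_head(head)
  if (length(anchor_radii) != head$B)
    stop_input("anchor_radii length must equal anchors per cell (B = ", head$B, ")")
  S <- head$S; B <- head$B; C <- head$C
  off <- cell_offsets(S, B)
  pr <- array(rep(anchor_radii, each = S * S), c(S, S, B))
  cx <- (sigmoid(head$t_x) + off$cx) * head$stride
  cy <- (sigmoid(head$t_y) + off$cy) * head$stride
  r <- pr * exp(head$t_r)
  conf <- sigmoid(head$t_conf)
  probs <- sigmoid(head$t_class)
  out <- data.frame(
    cx = as.vector(cx), cy = as.vector(cy), r = as.vector(r),
    confidence = as.vector(conf),
    cell_x = as.vector(off$cx), cell_y = as.vector(off$cy),
    anchor = as.vector(array(rep(seq_len(B), each = S * S), c(S, S, B)))
  )
  pm <- matrix(probs, nrow = S * S * B, ncol = C)
  colnames(pm) <- paste0("p", seq_len(C))
  out <- cbind(out, as.data.frame(pm))
  out$class_id <- max.col(pm, ties.method = "first")
  out[out$confidence >= conf_thresh, , drop = FALSE]
}

#' Encode a ground-truth circle as raw head coordinates
#'
#' Exact inverse of the decoding of [decode_head()] for one slot:
#' `t_x = logit(cx / stride - cell_x)`, likewise for `t_y`, and
#' `t_r = log(r / anchor_radius)`. The ground-truth center must lie inside
#' the given cell; a center exactly on a cell boundary sits at a logit
#' singularity and is nudged inward by `eps` cell units.
#'
#' @param gt One-row circle data frame (see [circle_box()]), `r > 0`.
#' @param anchor_radius Prior radius (pixels), positive.
#' @param cell Integer cell indices `c(cell_x, cell_y)`, 0-based.
#' @param stride Pixels per cell.
#' @param eps Boundary nudge in cell units (default `1e-6`).
#' @return Named numeric vector `c(tx, ty, tr)`.
#' @export
encode_box <- function(gt, anchor_radius, cell, stride, eps = 1e-6) {
  gt <- as_circle_df(gt)
  if (nrow(gt) != 1L) stop_input("encode_box expects a single ground truth")
  if (gt$r <= 0) stop_input("ground-truth radius must be positive to encode")
  if (anchor_radius <= 0) stop_input("anchor radius must be positive")
  ux <- gt$cx / stride - cell[1]
  uy <- gt$cy / stride - cell[2]
  if (ux < -eps || ux > 1 + eps || uy < -eps || uy > 1 + eps)
    stop_input("ground-truth center does not lie inside the given cell")
  ux <- clamp(ux, eps, 1 - eps)
  uy <- clamp(uy, eps, 1 - eps)
  c(tx = stats::qlogis(ux), ty = stats::qlogis(uy),
    tr = log(gt$r / anchor_radius))
}

# Anchor radii per scale, coarse (largest stride) to fine, from an
# anchor_set; strides must be sorted decreasing.
anchors_by_scale <- function(anchors, strides) {
  if (!inherits(anchors, "anchor_set") || anchors$shape != "circle")
    stop_input("a circular anchor_set is required")
  groups <- list(anchors$scale_assignment$coarse,
                 anchors$scale_assignment$mid,
                 anchors$scale_assignment$fine)
  if (length(strides) != 3L) stop_input("exactly three scale strides expected")
  lapply(groups, function(ii) anchors$dims[ii])
}

#' Assign ground truths to head slots
#'
#' Each ground-truth circle is made the responsibility of exactly one
#' (scale, cell, anchor) slot: the anchor with the highest concentric IoU
#' to the ground-truth radius determines the scale and within-scale anchor
#' index, and the cell is the one containing the center at that scale. The
#' responsible slot receives the object mask, the encoded coordinate
#' targets (center in grid units, radius in pixels), a confidence target of
#' 1 and a one-hot class target; every other slot carries the no-object
#' mask. When two ground truths map to the same slot the later one (input
#' order) wins and the earlier is demoted with a warning.
#'
#' @param gts Data frame of ground-truth circles (`cx`, `cy`, `r`,
#'   optional `class_id`).
#' @param anchors Circular [anchor_set()] covering all scales.
#' @param image_size Image side length in pixels (default 416).
#' @param strides Pixels per cell for the three scales, coarse to fine
#'   (default `c(32, 16, 8)`).
#' @param n_classes Number of classes (default 1).
#' @return A list of three per-scale target sets (class
#'   `target_tensor`), each a list with `S`, `B`, `stride`,
#'   `anchor_radii` and arrays `obj`, `noobj`, `x`, `y`, `r`, `C`, `pcls`;
#'   the attribute `"n_assigned"` counts responsible slots and
#'   `"demoted"` the ground truths displaced by collisions.
#' @export
assign_targets <- function(gts, anchors, image_size = 416,
                           strides = c(32, 16, 8), n_classes = 1) {
  gts <- gts[, intersect(c("cx", "cy", "r", "class_id"), names(gts)), drop = FALSE]
  gdf <- as_circle_df(gts)
  if (any(gdf$cx < 0 | gdf$cx > image_size | gdf$cy < 0 | gdf$cy > image_size))
    stop_input("ground-truth centers must lie within the image")
  cls <- if ("class_id" %in% names(gts)) as.integer(gts$class_id) else
    rep(1L, nrow(gdf))
  per_scale_radii <- anchors_by_scale(anchors, strides)
  all_radii <- unlist(per_scale_radii)
  scale_of <- rep(seq_len(3), lengths(per_scale_radii))
  slot_of <- unlist(lapply(lengths(per_scale_radii), seq_len))

  scales <- lapply(seq_len(3), function(s) {
    S <- as.integer(image_size / strides[s])
    B <- length(per_scale_radii[[s]])
    list(S = S, B = B, stride = strides[s], anchor_radii = per_scale_radii[[s]],
         obj = array(FALSE, c(S, S, B)), noobj = array(TRUE, c(S, S, B)),
         x = array(0, c(S, S, B)), y = array(0, c(S, S, B)),
         r = array(0, c(S, S, B)), C = array(0, c(S, S, B)),
         pcls = array(0, c(S, S, B, n_classes)))
  })

  owner <- list()  # slot key -> gt index, for collision reporting
  demoted <- 0L
  for (g in seq_len(nrow(gdf))) {
    iou <- concentric_iou(gdf$r[g], all_radii, "circle")
    j <- which.max(iou)
    s <- scale_of[j]; b <- slot_of[j]
    sc <- scales[[s]]
    ix <- clamp(floor(gdf$cx[g] / sc$stride), 0, sc$S - 1)
    iy <- clamp(floor(gdf$cy[g] / sc$stride), 0, sc$S - 1)
    key <- paste(s, iy, ix, b, sep = ":")
    if (!is.null(owner[[key]])) {
      warning("ground truth ", owner[[key]], " demoted: slot (scale ", s,
              ", cell ", ix, ",", iy, ", anchor ", b,
              ") re-assigned to ground truth ", g, call. = FALSE)
      demoted <- demoted + 1L
    }
    owner[[key]] <- g
    sc$obj[iy + 1, ix + 1, b] <- TRUE
    sc$noobj[iy + 1, ix + 1, b] <- FALSE
    sc$x[iy + 1, ix + 1, b] <- gdf$cx[g] / sc$stride
    sc$y[iy + 1, ix + 1, b] <- gdf$cy[g] / sc$stride
    sc$r[iy + 1, ix + 1, b] <- gdf$r[g]
    sc$C[iy + 1, ix + 1, b] <- 1
    sc$pcls[iy + 1, ix + 1, b, ] <- 0
    sc$pcls[iy + 1, ix + 1, b, cls[g]] <- 1
    scales[[s]] <- sc
  }
  scales <- lapply(scales, function(sc) structure(sc, class = "target_tensor"))
  structure(scales, n_assigned = sum(vapply(scales, function(sc) sum(sc$obj), 0)),
            demoted = demoted)
}

as_scale_list <- function(x, cls) {
  if (inherits(x, cls)) list(x) else x
}

decoded_quantities <- function(head, target, eps) {
  off <- cell_offsets(head$S, head$B)
  pr <- array(rep(target$anchor_radii, each = head$S * head$S),
              c(head$S, head$S, head$B))
  list(
    xh = sigmoid(head$t_x) + off$cx,
    yh = sigmoid(head$t_y) + off$cy,
    rh = pr * exp(head$t_r),
    ch = clamp(sigmoid(head$t_conf), eps, 1 - eps),
    ph = clamp(sigmoid(head$t_class), eps, 1 - eps)
  )
}

#' Detection loss over decoded circular predictions
#'
#' The training objective for circular-box prediction, a sum of five terms
#' over all `S^2 * B` slots of every scale:
#' a weighted squared error on the decoded center `(x_hat, y_hat)` in grid
#' units over responsible (object) slots; a weighted squared error on the
#' decoded radius `r_hat` in pixels over object slots; a cross-entropy
#' confidence term `-C * log(C_hat)` over object slots; a down-weighted
#' no-object confidence term `-(1 - C) * log(1 - C_hat)`; and a per-class
#' binary cross-entropy over object slots. The coordinate weight
#' `lambda_coord = 5` and no-object weight `lambda_noobj = 0.5` counteract
#' the imbalance between the few responsible slots and the many empty ones.
#' Probabilities are clipped to `[eps, 1 - eps]` before logs.
#'
#' The reported components carry their lambda weights, so `total` is their
#' plain sum and doubling `lambda_coord` doubles the coordinate components
#' only.
#'
#' @param heads A [head_output()] or list of them, one per scale.
#' @param targets Matching [assign_targets()] output (or a single
#'   `target_tensor`).
#' @param lambda_coord Coordinate-loss weight (default 5).
#' @param lambda_noobj No-object confidence weight (default 0.5).
#' @param eps Probability clip (default `1e-7`).
#' @return A list of class `loss_breakdown` with elements `coord_xy`,
#'   `coord_r`, `conf_obj`, `conf_noobj`, `class_term`, `total`,
#'   `lambda_coord`, `lambda_noobj`.
#' @export
total_loss <- function(heads, targets, lambda_coord = 5, lambda_noobj = 0.5,
                       eps = 1e-7) {
  heads <- as_scale_list(heads, "head_output")
  targets <- as_scale_list(targets, "target_tensor")
  if (length(heads) != length(targets))
    stop_input("heads and targets must have the same number of scales")
  acc <- c(coord_xy = 0, coord_r = 0, conf_obj = 0, conf_noobj = 0,
           class_term = 0)
  for (s in seq_along(heads)) {
    head <- check_head(heads[[s]]); tg <- targets[[s]]
    if (head$S != tg$S || head$B != tg$B)
      stop_input("head and target shapes disagree at scale ", s)
    q <- decoded_quantities(head, tg, eps)
    obj <- tg$obj; noobj <- tg$noobj
    acc["coord_xy"] <- acc["coord_xy"] + lambda_coord *
      sum(((tg$x - q$xh)^2 + (tg$y - q$yh)^2)[obj])
    acc["coord_r"] <- acc["coord_r"] + lambda_coord * sum(((tg$r - q$rh)^2)[obj])
    acc["conf_obj"] <- acc["conf_obj"] + sum((-tg$C * log(q$ch))[obj])
    acc["conf_noobj"] <- acc["conf_noobj"] + lambda_noobj *
      sum((-(1 - tg$C) * log(1 - q$ch))[noobj])
    objc <- array(obj, dim = dim(tg$pcls))  # recycle mask over classes
    acc["class_term"] <- acc["class_term"] +
      sum((-tg$pcls * log(q$ph) - (1 - tg$pcls) * log(1 - q$ph))[objc])
  }
  structure(as.list(c(acc, total = sum(acc),
                      lambda_coord = lambda_coord, lambda_noobj = lambda_noobj)),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat("Detection loss (lambda_coord =", x$lambda_coord,
      ", lambda_noobj =", x$lambda_noobj, ")\n")
  for (nm in c("coord_xy", "coord_r", "conf_obj", "conf_noobj", "class_term"))
    cat(sprintf("  %-10s %g\n", nm, x[[nm]]))
  cat(sprintf("  %-10s %g\n", "total", x$total))
  invisible(x)
}

#' Analytic gradient of the detection loss
#'
#' Partial derivatives of [total_loss()] with respect to every raw head
#' value, per scale. Used to verify the sigmoid/exponential decoding chain
#' against finite differences; probability clipping is ignored in the
#' derivative (exact away from the clip region).
#'
#' @inheritParams total_loss
#' @return A list (one element per scale) of lists of arrays `t_x`, `t_y`,
#'   `t_r`, `t_conf`, `t_class` matching the head shapes.
#' @export
head_gradient <- function(heads, targets, lambda_coord = 5, lambda_noobj = 0.5,
                          eps = 1e-7) {
  heads <- as_scale_list(heads, "head_output")
  targets <- as_scale_list(targets, "target_tensor")
  out <- vector("list", length(heads))
  for (s in seq_along(heads)) {
    head <- check_head(heads[[s]]); tg <- targets[[s]]
    q <- decoded_quantities(head, tg, eps)
    sx <- sigmoid(head$t_x); sy <- sigmoid(head$t_y)
    obj <- tg$obj; noobj <- tg$noobj
    gx <- lambda_coord * 2 * (q$xh - tg$x) * sx * (1 - sx) * obj
    gy <- lambda_coord * 2 * (q$yh - tg$y) * sy * (1 - sy) * obj
    gr <- lambda_coord * 2 * (q$rh - tg$r) * q$rh * obj
    gc <- (-tg$C * (1 - q$ch)) * obj + lambda_noobj * (1 - tg$C) * q$ch * noobj
    objc <- array(obj, dim = dim(tg$pcls))
    gp <- (q$ph - tg$pcls) * objc
    out[[s]] <- list(t_x = gx, t_y = gy, t_r = gr, t_conf = gc, t_class = gp)
  }
  out
}
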