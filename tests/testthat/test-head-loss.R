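# Minimal hand-built single-slot target for loss arithmetic tests.
slot_target <- function(x = 0.5, y = 0.5, r = 10, anchor = 10, stride = 32,
                        obj = TRUE, p = 1) {
  structure(list(
    S = 1L, B = 1L, stride = stride, anchor_radii = anchor,
    obj = array(obj, c(1, 1, 1)), noobj = array(!obj, c(1, 1, 1)),
    x = array(x, c(1, 1, 1)), y = array(y, c(1, 1, 1)),
    r = array(r, c(1, 1, 1)), C = array(as.numeric(obj), c(1, 1, 1)),
    pcls = array(p, c(1, 1, 1, 1))
  ), class = "target_tensor")
}

test_that("decoding follows the sigmoid/exponential parameterization", {
  h <- head_output(13, 1, 1, stride = 32)
  d <- decode_head(h, anchor_radii = 10)
  row <- d[d$cell_x == 3 & d$cell_y == 4, ]
  expect_equal(row$cx, 3.5 * 32)
  expect_equal(row$cy, 4.5 * 32)
  expect_equal(row$r, 10)              # t_r = 0 -> prior radius
  expect_equal(row$confidence, 0.5)
  h$t_r[] <- log(2)
  expect_equal(decode_head(h, 10)$r[1], 20)
  expect_error(decode_head(h, c(10, 20)), "anchor_radii")
})

test_that("encode is the exact inverse of decode", {
  # fixed point: center of the cell, radius = anchor
  t0 <- encode_box(circle_box(3.5 * 32, 4.5 * 32, 10), 10, c(3, 4), 32)
  expect_equal(unname(t0), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(unname(encode_box(circle_box(16, 16, 20), 10, c(0, 0), 32)["tr"]),
               log(2))
  set.seed(99)
  for (i in 1:300) {
    S <- sample(c(13, 26, 52), 1)
    stride <- 416 / S
    cell <- c(sample(0:(S - 1), 1), sample(0:(S - 1), 1))
    gt <- circle_box((cell[1] + runif(1, 1e-4, 1 - 1e-4)) * stride,
                     (cell[2] + runif(1, 1e-4, 1 - 1e-4)) * stride,
                     runif(1, 2, 80))
    pr <- runif(1, 5, 60)
    t <- encode_box(gt, pr, cell, stride)
    h <- head_output(S, 1, 1, stride = stride)
    h$t_x[cell[2] + 1, cell[1] + 1, 1] <- t["tx"]
    h$t_y[cell[2] + 1, cell[1] + 1, 1] <- t["ty"]
    h$t_r[cell[2] + 1, cell[1] + 1, 1] <- t["tr"]
    d <- decode_head(h, pr)
    row <- d[d$cell_x == cell[1] & d$cell_y == cell[2], ]
    expect_equal(row$cx, gt$cx, tolerance = 1e-9)
    expect_equal(row$cy, gt$cy, tolerance = 1e-9)
    expect_equal(row$r, gt$r, tolerance = 1e-9)
  }
  expect_error(encode_box(circle_box(200, 16, 5), 10, c(0, 0), 32), "cell")
})

test_that("each ground truth is assigned to exactly one slot", {
  anc <- anchor_set(c(8, 12, 18, 26, 36, 48, 62, 78, 95), "circle")
  gt <- circle_box(100, 120, 25); gt$class_id <- 1L
  tg <- assign_targets(gt, anc, 416)
  expect_equal(attr(tg, "n_assigned"), 1)
  total_obj <- sum(vapply(tg, function(s) sum(s$obj), 0))
  total_noobj <- sum(vapply(tg, function(s) sum(s$noobj), 0))
  total_slots <- sum(vapply(tg, function(s) s$S^2 * s$B, 0))
  expect_equal(total_obj, 1)
  expect_equal(total_obj + total_noobj, total_slots)  # strict partition
})

test_that("a ground truth matching an anchor exactly lands on that anchor", {
  anc <- anchor_set(c(8, 12, 18, 26, 36, 48, 62, 78, 95), "circle")
  gt <- circle_box(210, 210, 48)   # radius equals anchor 6 exactly
  tg <- assign_targets(gt, anc, 416)
  # anchor 48 is in the mid scale group (4th..6th by size)
  expect_equal(sum(tg[[2]]$obj), 1)
  b <- which(apply(tg[[2]]$obj, 3, any))
  expect_equal(tg[[2]]$anchor_radii[b], 48)
})

test_that("multi-object assignment equals the argmax-IoU oracle", {
  set.seed(17)
  anc <- anchor_set(c(8, 12, 18, 26, 36, 48, 62, 78, 95), "circle")
  strides <- c(32, 16, 8)
  groups <- list(anc$scale_assignment$coarse, anc$scale_assignment$mid,
                 anc$scale_assignment$fine)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    gt <- circle_box(runif(n, 10, 400), runif(n, 10, 400), runif(n, 6, 100))
    tg <- suppressWarnings(assign_targets(gt, anc, 416))
    # oracle: exhaustive best-IoU anchor per ground truth, last writer wins
    expected <- list()
    for (g in seq_len(n)) {
      best <- -1; bj <- 0
      for (j in seq_along(anc$dims)) {
        iou <- (min(gt$r[g], anc$dims[j]) / max(gt$r[g], anc$dims[j]))^2
        if (iou > best) { best <- iou; bj <- j }
      }
      s <- which(vapply(groups, function(gr) bj %in% gr, TRUE))
      b <- match(bj, groups[[s]])
      key <- paste(s, floor(gt$cx[g] / strides[s]), floor(gt$cy[g] / strides[s]), b)
      expected[[key]] <- g
    }
    got <- sum(vapply(tg, function(s) sum(s$obj), 0))
    expect_equal(got, length(expected))
    for (key in names(expected)) {
      parts <- as.integer(strsplit(key, " ")[[1]])
      s <- parts[1]; ix <- parts[2]; iy <- parts[3]; b <- parts[4]
      expect_true(tg[[s]]$obj[iy + 1, ix + 1, b])
      g <- expected[[key]]
      expect_equal(tg[[s]]$r[iy + 1, ix + 1, b], gt$r[g])
    }
  }
})

test_that("colliding ground truths warn and the later one wins", {
  anc <- anchor_set(c(8, 12, 18, 26, 36, 48, 62, 78, 95), "circle")
  gt <- circle_box(c(100, 101), c(100, 101), c(95, 96))
  expect_warning(tg <- assign_targets(gt, anc, 416), "demoted")
  expect_equal(attr(tg, "n_assigned"), 1)
  obj_r <- unlist(lapply(tg, function(s) s$r[s$obj]))
  expect_equal(obj_r, 96)
})

test_that("loss vanishes at the optimum and matches hand arithmetic", {
  # near-perfect prediction: every term at its optimum
  tgt <- slot_target(x = 0.5, y = 0.5, r = 10, anchor = 10)
  h <- head_output(1, 1, 1, stride = 32)
  h$t_conf[] <- 20; h$t_class[] <- 20   # sigmoid ~ 1 - 2e-9
  l <- total_loss(h, tgt)
  expect_lt(l$total, 1e-5)

  # worked single-slot example: x off by one grid unit, C_hat = p_hat = 0.5.
  # Independent scalar evaluation of the printed loss:
  #   5 * (1^2 + 0^2)  +  5 * 0^2  +  (-log 0.5)  +  0  +
  #   (-1 * log 0.5 - (1 - 1) * log(1 - 0.5))
  expected <- 5 * (1^2 + 0^2) + 5 * 0^2 + (-log(0.5)) +
    (-1 * log(0.5) - 0 * log(0.5))
  tgt2 <- slot_target(x = 1.5, y = 0.5, r = 10, anchor = 10)
  h2 <- head_output(1, 1, 1, stride = 32)   # all raw zeros
  l2 <- total_loss(h2, tgt2)
  expect_equal(l2$total, expected, tolerance = 1e-9)
  expect_equal(l2$coord_xy, 5)
  expect_equal(l2$conf_obj, log(2))
  expect_equal(l2$class_term, log(2))
  expect_equal(l2$conf_noobj, 0)

  # doubling lambda_coord doubles the coordinate components only
  l3 <- total_loss(h2, tgt2, lambda_coord = 10)
  expect_equal(l3$coord_xy, 2 * l2$coord_xy)
  expect_equal(l3$coord_r, 2 * l2$coord_r)
  expect_equal(l3$conf_obj, l2$conf_obj)
  expect_equal(l3$class_term, l2$class_term)

  # components are non-negative and total is their sum
  expect_true(all(unlist(l2[c("coord_xy", "coord_r", "conf_obj",
                              "conf_noobj", "class_term")]) >= 0))
  expect_equal(l2$total, l2$coord_xy + l2$coord_r + l2$conf_obj +
                 l2$conf_noobj + l2$class_term)

  h_bad <- head_output(1, 1, 1, stride = 32, fill = NaN)
  expect_error(total_loss(h_bad, tgt2), "finite")
})

test_that("analytic loss gradient matches central finite differences", {
  set.seed(31)
  anc <- anchor_set(c(8, 12, 18, 26, 36, 48, 62, 78, 95), "circle")
  gt <- circle_box(runif(4, 20, 400), runif(4, 20, 400), runif(4, 8, 90))
  tg <- suppressWarnings(assign_targets(gt, anc, 416))
  heads <- lapply(tg, function(s) {
    h <- head_output(s$S, s$B, 1, stride = s$stride)
    h$t_x[] <- runif(length(h$t_x), -1.5, 1.5)
    h$t_y[] <- runif(length(h$t_y), -1.5, 1.5)
    h$t_r[] <- runif(length(h$t_r), -0.5, 0.5)
    h$t_conf[] <- runif(length(h$t_conf), -1.5, 1.5)
    h$t_class[] <- runif(length(h$t_class), -1.5, 1.5)
    h
  })
  grad <- head_gradient(heads, tg)
  fd <- function(s, field, idx, hstep = 1e-5) {
    hp <- heads; hp[[s]][[field]][idx] <- hp[[s]][[field]][idx] + hstep
    hm <- heads; hm[[s]][[field]][idx] <- hm[[s]][[field]][idx] - hstep
    (total_loss(hp, tg)$total - total_loss(hm, tg)$total) / (2 * hstep)
  }
  for (trial in 1:30) {
    s <- sample(3, 1)
    field <- sample(c("t_x", "t_y", "t_r", "t_conf", "t_class"), 1)
    idx <- sample(length(heads[[s]][[field]]), 1)
    g_an <- grad[[s]][[field]][idx]
    g_fd <- fd(s, field, idx)
    denom <- max(abs(g_an), abs(g_fd), 1e-6)
    expect_lt(abs(g_an - g_fd) / denom, 1e-4)
  }
})
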