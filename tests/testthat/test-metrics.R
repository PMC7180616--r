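make_dets <- function(cx, r, conf, cy = 0) {
  d <- circle_box(cx, cy, r)
  d$confidence <- conf
  d
}

test_that("matching labels detections and satisfies the count identities", {
  gts <- circle_box(c(0, 100, 200), 0, 10)
  dets <- make_dets(c(0, 100), 10, c(1, 1))
  m <- match_detections(dets, gts)
  expect_equal(c(m$tp, m$fp, m$fn), c(2, 0, 1))
  far <- make_dets(c(0, 100, 500), 10, c(0.9, 0.8, 0.7))
  m2 <- match_detections(far, gts)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(2, 1, 1))
  expect_equal(m2$det_label, c("TP", "TP", "FP"))
  set.seed(13)
  for (i in 1:25) {
    g <- random_detections(sample(1:8, 1)); g$confidence <- NULL
    d <- random_detections(sample(0:12, 1))
    m3 <- match_detections(d, g, iou_thresh = 0.4)
    expect_equal(m3$tp + m3$fn, nrow(g))
    expect_equal(m3$tp + m3$fp, nrow(d))
    expect_lte(m3$tp, nrow(g))
  }
})

test_that("recall/precision/F1 follow their defining ratios", {
  gts <- circle_box(c(0, 100, 200), 0, 10)
  dets <- make_dets(c(0, 100, 500), 10, c(0.9, 0.85, 0.95))
  r <- prf_at_threshold(dets, gts, conf_thresh = 0.5)
  expect_equal(r$recall, 2 / 3)
  expect_equal(r$precision, 2 / 3)
  expect_equal(r$f1, 2 / 3)
  # everything below the confidence threshold
  low <- prf_at_threshold(dets, gts, conf_thresh = 0.99)
  expect_equal(low$recall, 0)
  expect_equal(low$precision, 0)
  expect_false(low$precision_defined)
  expect_equal(low$f1, 0)
  expect_error(prf_at_threshold(dets, gts[0, ], 0.5), "ground truths")
})

test_that("average precision matches hand-worked and trivial cases", {
  gts <- circle_box(c(0, 100), 0, 10)
  # conf .9 TP, conf .8 FP, conf .7 TP -> points (0.5,1), (0.5,0.5), (1,2/3)
  dets <- make_dets(c(0, 500, 100), 10, c(0.9, 0.8, 0.7))
  ap <- average_precision(pr_curve(dets, gts))
  expect_equal(ap, 0.5 * 1 + 0.5 * (2 / 3))
  # perfect detector
  perf <- make_dets(c(0, 100), 10, c(1, 0.9))
  expect_equal(average_precision(pr_curve(perf, gts)), 1)
  # single TP, single GT
  one <- make_dets(0, 10, 0.4)
  expect_equal(average_precision(pr_curve(one, circle_box(0, 0, 10))), 1)
  expect_warning(ap0 <- average_precision(data.frame()), "empty")
  expect_equal(ap0, 0)
})

test_that("AP equals exhaustive threshold enumeration on small instances", {
  set.seed(29)
  for (i in 1:150) {
    n_gt <- sample(2:3, 1)
    gts <- circle_box(seq(0, by = 60, length.out = n_gt), 0,
                      runif(n_gt, 8, 14))
    n_det <- sample(1:6, 1)
    near <- sample(n_gt, n_det, replace = TRUE)
    dets <- circle_box(gts$cx[near] + runif(n_det, -25, 25),
                       runif(n_det, -8, 8),
                       gts$r[near] * exp(runif(n_det, -0.5, 0.5)))
    dets$confidence <- sample(seq(0.1, 0.9, by = 0.2), n_det, replace = TRUE)
    ap_pkg <- average_precision(pr_curve(dets, gts))
    expect_equal(ap_pkg, ap_enumeration(dets, gts), tolerance = 1e-12)
  }
})

test_that("AP respects its structural invariants", {
  set.seed(59)
  gts <- circle_box(seq(0, 300, by = 60), 0, 10)
  dets <- circle_box(gts$cx + rnorm(6, 0, 2), rnorm(6, 0, 2),
                     gts$r * exp(rnorm(6, 0, 0.1)))
  dets$confidence <- runif(6, 0.3, 0.95)
  curve <- pr_curve(dets, gts)
  # interpolated envelope non-increasing in recall
  expect_true(all(diff(curve$p_interp) <= 1e-12))
  ap <- average_precision(curve)
  expect_gte(ap, 0); expect_lte(ap, 1)
  # monotone confidence rescaling leaves AP unchanged
  resc <- dets; resc$confidence <- dets$confidence^3
  expect_equal(average_precision(pr_curve(resc, gts)), ap)
  # appending a lowest-confidence FP never increases AP
  fp <- circle_box(900, 0, 10); fp$confidence <- 0.01
  expect_lte(average_precision(pr_curve(rbind(dets, fp), gts)), ap)
  # appending a lowest-confidence TP (on a missed GT) never decreases AP
  gts2 <- rbind(gts, circle_box(600, 0, 10))
  ap2 <- average_precision(pr_curve(dets, gts2))
  tp <- circle_box(600, 0, 10); tp$confidence <- 0.01
  expect_gte(average_precision(pr_curve(rbind(dets, tp), gts2)) + 1e-12, ap2)
})

test_that("sub-dataset AP sampling is deterministic and consistent", {
  set.seed(41)
  imgs <- sprintf("img%03d", 1:30)
  gts <- do.call(rbind, lapply(imgs, function(id) {
    g <- circle_box(runif(4, 20, 380), runif(4, 20, 380), runif(4, 10, 30))
    g$image_id <- id
    g
  }))
  dets <- perturb_detections(gts, sigma_center = 2, miss_rate = 0.1,
                             fp_rate = 0.1, seed = 5)
  a1 <- subsample_ap(dets, gts, n_subsets = 5, subset_size = 10, seed = 8)
  a2 <- subsample_ap(dets, gts, n_subsets = 5, subset_size = 10, seed = 8)
  expect_identical(a1, a2)
  # whole-set subset equals the global AP
  whole <- subsample_ap(dets, gts, n_subsets = 1, subset_size = 30, seed = 1)
  expect_equal(whole, average_precision(pr_curve(dets, gts)))
  expect_error(subsample_ap(dets, gts, subset_size = 100), "fewer images")
})

test_that("Wilcoxon signed-rank: degenerate, exact and approximate regimes", {
  same <- wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3))
  expect_true(same$degenerate)
  expect_equal(same$p_value, 1)
  # six all-positive differences: W = 21, two-sided exact p = 2/64
  w6 <- wilcoxon_signed_rank(c(5, 6, 7, 8, 9, 10), c(1, 2, 3, 4, 5, 6))
  expect_equal(w6$statistic, 21)
  expect_equal(w6$p_value, 2 / 2^6)
  expect_equal(w6$method, "exact")
  # agreement with the stats oracle on tie-free data
  set.seed(71)
  for (i in 1:10) {
    a <- rnorm(10); b <- rnorm(10)
    ours <- wilcoxon_signed_rank(a, b)
    ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
  # normal approximation close to enumeration at n = 12
  for (i in 1:10) {
    a <- rnorm(12); b <- rnorm(12)
    ex <- wilcoxon_signed_rank(a, b, method = "exact")
    ap <- wilcoxon_signed_rank(a, b, method = "normal")
    expect_lt(abs(ex$p_value - ap$p_value), 0.02)
  }
})
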