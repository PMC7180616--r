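test_that("circle overlap area matches closed-form and degenerate cases", {
  # full self-overlap
  expect_equal(circle_overlap_area(circle_box(0, 0, 1), circle_box(0, 0, 1)),
               pi)
  # externally tangent: zero-measure overlap
  expect_equal(circle_overlap_area(circle_box(0, 0, 1), circle_box(2, 0, 1)),
               0)
  # unit circles at distance 1: standard lens area 2*pi/3 - sqrt(3)/2
  expect_equal(circle_overlap_area(circle_box(0, 0, 1), circle_box(1, 0, 1)),
               2 * pi / 3 - sqrt(3) / 2, tolerance = 1e-12)
  # containment
  expect_equal(circle_overlap_area(circle_box(0, 0, 2), circle_box(0.5, 0, 1)),
               pi)
  # degenerate radius
  expect_equal(circle_overlap_area(circle_box(0, 0, 0), circle_box(0, 0, 1)),
               0)
})

test_that("circle IoU matches known values and is symmetric", {
  a <- circle_box(0, 0, 1); b <- circle_box(1, 0, 1)
  lens <- 2 * pi / 3 - sqrt(3) / 2
  expect_equal(circle_iou(a, a), 1)
  expect_equal(circle_iou(a, b), lens / (2 * pi - lens), tolerance = 1e-12)
  expect_equal(circle_iou(circle_box(0, 0, 2), circle_box(0, 0, 1)), 0.25)
  # containment equals r^2/R^2 in both orientations
  expect_equal(circle_iou(circle_box(0, 0, 5), circle_box(1, 1, 2)),
               (2 / 5)^2, tolerance = 1e-12)
  expect_equal(circle_iou(circle_box(1, 1, 2), circle_box(0, 0, 5)),
               (2 / 5)^2, tolerance = 1e-12)
  # both radii zero: defined as 0
  expect_equal(circle_iou(circle_box(0, 0, 0), circle_box(0, 0, 0)), 0)
})

test_that("circle IoU is symmetric, bounded and monotone in distance", {
  set.seed(11)
  for (i in 1:50) {
    p <- random_circle_pair()
    iou_ab <- circle_iou(p$a, p$b)
    expect_equal(iou_ab, circle_iou(p$b, p$a))
    expect_gte(iou_ab, 0)
    expect_lte(iou_ab, 1)
    if (p$regime == "disjoint") expect_equal(iou_ab, 0)
  }
  # non-increasing along growing center distance, fixed radii
  R <- 3; r <- 2
  d <- seq(0, R + r, length.out = 60)
  iou <- circle_iou(circle_box(0, 0, R), circle_box(d, 0, r))
  expect_true(all(diff(iou) <= 1e-12))
})

test_that("lens formula is continuous at the regime boundaries", {
  R <- 3; r <- 1.5
  eps <- 1e-8
  inner <- circle_overlap_area(circle_box(0, 0, R),
                               circle_box(R - r + eps, 0, r))
  expect_equal(inner, pi * r^2, tolerance = 1e-6)
  outer_ <- circle_overlap_area(circle_box(0, 0, R),
                                circle_box(R + r - eps, 0, r))
  expect_lt(outer_, 1e-9 * pi * r^2 + 1e-6)
})

test_that("circle areas agree with the Monte-Carlo oracle", {
  set.seed(21)
  for (i in 1:40) {
    p <- random_circle_pair()
    mc <- mc_circle_overlap(p$a, p$b, n = 2e5)
    expect_lt(abs(circle_overlap_area(p$a, p$b) - mc$est),
              3 * mc$se + 1e-9)
  }
})

test_that("rect IoU matches hand values and the rasterized oracle", {
  expect_equal(rect_iou(rect_box(0, 0, 2, 2), rect_box(0, 0, 2, 2)), 1)
  expect_equal(rect_iou(rect_box(0, 0, 2, 2), rect_box(2, 0, 2, 2)), 0)
  expect_equal(rect_iou(rect_box(0, 0, 2, 2), rect_box(1, 1, 2, 2)), 1 / 7)
  expect_equal(rect_iou(rect_box(0, 0, 0, 0), rect_box(0, 0, 0, 0)), 0)
  set.seed(31)
  for (i in 1:25) {
    a <- rect_box(sample(0:10, 1), sample(0:10, 1), sample(1:8, 1), sample(1:8, 1))
    b <- rect_box(sample(0:10, 1), sample(0:10, 1), sample(1:8, 1), sample(1:8, 1))
    # integer-aligned: shift centers so edges land on integers
    a$cx <- a$cx + a$w %% 2 / 2; a$cy <- a$cy + a$h %% 2 / 2
    b$cx <- b$cx + b$w %% 2 / 2; b$cy <- b$cy + b$h %% 2 / 2
    expect_equal(rect_iou(a, b), raster_rect_iou(a, b))
  }
})

test_that("shape conversions follow the stated modes and round-trip", {
  expect_equal(rect_to_circle(rect_box(0, 0, 4, 4))$r, 2)
  expect_equal(rect_to_circle(rect_box(0, 0, 2, 4), "mean")$r, 1.5)
  expect_equal(rect_to_circle(rect_box(0, 0, 2, 4), "min")$r, 1)
  expect_equal(rect_to_circle(rect_box(0, 0, 2, 4), "max")$r, 2)
  expect_equal(rect_to_circle(rect_box(0, 0, 3, 4), "circumscribed")$r, 2.5)
  expect_equal(circle_to_rect(circle_box(0, 0, 1)), rect_box(0, 0, 2, 2))
  expect_equal(circle_to_rect(circle_box(5, 5, 0)), rect_box(5, 5, 0, 0))
  c0 <- circle_box(3, 7, 4.25)
  expect_equal(rect_to_circle(circle_to_rect(c0), "mean"), c0)
  expect_error(rect_to_circle(rect_box(0, 0, 1, 1), "bogus"))
})

test_that("invalid geometry inputs are rejected", {
  expect_error(circle_box(0, 0, -1), "non-negative")
  expect_error(circle_box(NA, 0, 1), "finite")
  expect_error(circle_box(Inf, 0, 1), "finite")
  expect_error(rect_box(0, 0, -2, 1), "non-negative")
  expect_error(circle_iou(data.frame(x = 1), circle_box(0, 0, 1)))
})
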