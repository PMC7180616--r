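#' Synthetic scene specification
#'
#' Parameters for the fixture generator, which emulates the disturbance
#' structure of field images of round fruit: quasi-circular objects with
#' size variation, deliberate overlap between neighbours, partial occlusion
#' by leaf-like patches, and two illumination regimes (direct sunlight:
#' bright, high contrast; shading: dark, flat). The generator stands in for
#' field imagery when exercising the detection pipeline end to end; it does
#' not attempt photorealism.
#'
#' @param image_size Image side length in pixels (default 416, the usual
#'   detector input size).
#' @param n_objects Object count, either a single count or a `c(min, max)`
#'   range sampled uniformly (default `c(3, 8)`).
#' @param radius_meanlog,radius_sdlog Log-normal radius distribution in
#'   pixels (defaults `log(28)` and 0.35, giving fruit radii mostly in
#'   15-55 px at the default image size).
#' @param overlap_fraction Probability that a new object is placed
#'   overlapping an existing one (default 0.3).
#' @param occluded_fraction Fraction of objects that receive a leaf-like
#'   occluder (default 0.5).
#' @param occlusion_severity Target covered fraction for occluded objects
#'   (default 0.6, i.e. past the 50% boundary that separates severe from
#'   slight occlusion).
#' @param brightness Named list of `c(mean, contrast)` pairs for the
#'   `sunlight` and `shading` regimes.
#' @param seed Integer seed; scenes are deterministic given the spec.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(image_size = 416, n_objects = c(3, 8),
                       radius_meanlog = log(28), radius_sdlog = 0.35,
                       overlap_fraction = 0.3,
                       occluded_fraction = 0.5, occlusion_severity = 0.6,
                       brightness = list(sunlight = c(mean = 0.70, contrast = 0.30),
                                         shading = c(mean = 0.35, contrast = 0.15)),
                       seed = 0) {
  if (overlap_fraction < 0 || overlap_fraction > 1 ||
      occluded_fraction < 0 || occluded_fraction > 1 ||
      occlusion_severity < 0 || occlusion_severity > 1)
    stop_input("fractions must lie in [0, 1]")
  if (radius_sdlog < 0) stop_input("radius_sdlog must be non-negative")
  structure(list(image_size = image_size, n_objects = n_objects,
                 radius_meanlog = radius_meanlog, radius_sdlog = radius_sdlog,
                 overlap_fraction = overlap_fraction,
                 occluded_fraction = occluded_fraction,
                 occlusion_severity = occlusion_severity,
                 brightness = brightness, seed = seed),
            class = "scene_spec")
}

# Disc pixel mask over a window; returns row/col index vectors and the
# logical mask. Pixel (row, col) has center (col - 0.5, row - 0.5).
disc_window <- function(cx, cy, r, H, W) {
  rows <- max(1L, floor(cy - r)):min(H, ceiling(cy + r))
  cols <- max(1L, floor(cx - r)):min(W, ceiling(cx + r))
  px <- outer(rep(1, length(rows)), cols - 0.5)
  py <- outer(rows - 0.5, rep(1, length(cols)))
  d2 <- (px - cx)^2 + (py - cy)^2
  list(rows = rows, cols = cols, mask = d2 <= r^2, d2 = d2)
}

ellipse_window <- function(cx, cy, a, b, phi, H, W) {
  ext <- max(a, b)
  rows <- max(1L, floor(cy - ext)):min(H, ceiling(cy + ext))
  cols <- max(1L, floor(cx - ext)):min(W, ceiling(cx + ext))
  px <- outer(rep(1, length(rows)), cols - 0.5) - cx
  py <- outer(rows - 0.5, rep(1, length(cols))) - cy
  u <- px * cos(phi) + py * sin(phi)
  v <- -px * sin(phi) + py * cos(phi)
  list(rows = rows, cols = cols, mask = (u / a)^2 + (v / b)^2 <= 1)
}

empty_gt_df <- function() {
  data.frame(image_id = character(0), cx = numeric(0), cy = numeric(0),
             r = numeric(0), class_id = integer(0),
             occlusion_fraction = numeric(0), pixel_area = numeric(0),
             occlusion_tag = character(0), illumination_tag = character(0))
}

#' Generate a synthetic fruit scene
#'
#' Renders a grayscale scene (matrix in `[0, 1]`, rows = y) containing
#' filled quasi-circular objects with radial shading over a cluttered
#' background, then draws elliptical "leaf" occluders over a subset of the
#' objects. Ground-truth circles are amodal: they describe the full fruit
#' extent even where it is hidden. Each object's occlusion fraction is
#' measured exactly from the rendered ownership masks (pixels captured by
#' later-drawn objects or occluders count as covered), and objects covered
#' by more than 50% are tagged `"severe"`, the rest `"slight"`.
#'
#' Placement is rejection-sampled; if a crowded scene cannot fit another
#' object after 1000 attempts the scene is generated with fewer objects
#' and a message is emitted.
#'
#' @param spec A [scene_spec()].
#' @param image_id Identifier stored in the ground-truth table.
#' @return A list with `image` (numeric matrix), `gts` (data frame with
#'   columns `image_id`, `cx`, `cy`, `r`, `class_id`,
#'   `occlusion_fraction`, `pixel_area`, `occlusion_tag`,
#'   `illumination_tag`) and `illumination` (the regime drawn for the
#'   scene).
#' @export
generate_scene <- function(spec, image_id = "scene") {
  stopifnot(inherits(spec, "scene_spec"))
  sz <- spec$image_size
  with_seed(spec$seed, {
    regime <- sample(c("sunlight", "shading"), 1L)
    br <- spec$brightness[[regime]]
    bmean <- br[["mean"]]; bcontr <- br[["contrast"]]

    # Background: coarse noise field upscaled, plus dim foliage clutter.
    cell <- 16L
    coarse <- matrix(stats::rnorm(ceiling(sz / cell)^2, 0, 1),
                     ceiling(sz / cell))
    bg <- kronecker(coarse, matrix(1, cell, cell))[1:sz, 1:sz]
    img <- clamp(bmean * 0.6 + 0.12 * bcontr * bg, 0, 1)
    for (i in seq_len(6)) {
      e <- ellipse_window(stats::runif(1, 0, sz), stats::runif(1, 0, sz),
                          stats::runif(1, 15, 60), stats::runif(1, 10, 40),
                          stats::runif(1, 0, pi), sz, sz)
      img[e$rows, e$cols][e$mask] <-
        clamp(bmean * 0.5 + stats::rnorm(1, 0, 0.05 + 0.1 * bcontr), 0, 1)
    }

    n_target <- if (length(spec$n_objects) == 2L)
      sample(spec$n_objects[1]:spec$n_objects[2], 1L) else spec$n_objects[1]

    cx <- cy <- r <- numeric(0)
    for (i in seq_len(n_target)) {
      placed <- FALSE
      for (att in seq_len(1000L)) {
        ri <- clamp(stats::rlnorm(1, spec$radius_meanlog, spec$radius_sdlog),
                    8, sz / 3)
        if (length(cx) > 0 && stats::runif(1) < spec$overlap_fraction) {
          j <- sample.int(length(cx), 1L)
          ang <- stats::runif(1, 0, 2 * pi)
          dd <- stats::runif(1, 0.65, 0.95) * (ri + r[j])
          xi <- cx[j] + dd * cos(ang); yi <- cy[j] + dd * sin(ang)
          ok <- xi > ri * 0.4 && xi < sz - ri * 0.4 &&
                yi > ri * 0.4 && yi < sz - ri * 0.4
        } else {
          xi <- stats::runif(1, ri * 0.6, sz - ri * 0.6)
          yi <- stats::runif(1, ri * 0.6, sz - ri * 0.6)
          ok <- length(cx) == 0 ||
            all(sqrt((cx - xi)^2 + (cy - yi)^2) >= (r + ri) * 1.02)
        }
        if (ok) {
          cx <- c(cx, xi); cy <- c(cy, yi); r <- c(r, ri)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        message("scene too crowded: placed ", length(cx), " of ", n_target,
                " objects")
        break
      }
    }
    n <- length(cx)

    # Painter's rendering with an ownership map for exact coverage.
    owner <- matrix(0L, sz, sz)
    area <- numeric(n)
    for (i in seq_len(n)) {
      w <- disc_window(cx[i], cy[i], r[i], sz, sz)
      area[i] <- sum(w$mask)
      tone <- clamp(bmean + 0.3 * bcontr + 0.15 * bcontr * stats::rnorm(1),
                    0.1, 1)
      shade <- tone * (1 - 0.45 * w$d2 / r[i]^2)
      sub_img <- img[w$rows, w$cols]
      sub_img[w$mask] <- clamp(shade[w$mask], 0, 1)
      img[w$rows, w$cols] <- sub_img
      sub_own <- owner[w$rows, w$cols]
      sub_own[w$mask] <- i
      owner[w$rows, w$cols] <- sub_own
    }

    # Leaf-like occluders over a subset, offset tuned by bisection so the
    # covered fraction of the target disc hits occlusion_severity.
    n_occ <- round(spec$occluded_fraction * n)
    occ_targets <- if (n_occ > 0) sample.int(n, n_occ) else integer(0)
    for (i in occ_targets) {
      a <- 1.4 * r[i]; b <- 1.05 * r[i]
      phi <- stats::runif(1, 0, pi)
      ang <- stats::runif(1, 0, 2 * pi)
      dw <- disc_window(cx[i], cy[i], r[i], sz, sz)
      cover_at <- function(t) {
        e <- ellipse_window(cx[i] + t * cos(ang), cy[i] + t * sin(ang),
                            a, b, phi, sz, sz)
        em <- matrix(FALSE, sz, sz)
        em[e$rows, e$cols] <- e$mask
        sum(em[dw$rows, dw$cols] & dw$mask) / max(1, sum(dw$mask))
      }
      lo <- 0; hi <- a + r[i]
      for (it in seq_len(10L)) {
        mid <- (lo + hi) / 2
        if (cover_at(mid) > spec$occlusion_severity) lo <- mid else hi <- mid
      }
      t_star <- (lo + hi) / 2
      e <- ellipse_window(cx[i] + t_star * cos(ang), cy[i] + t_star * sin(ang),
                          a, b, phi, sz, sz)
      tone <- clamp(bmean * 0.55 + 0.08 * bcontr * stats::rnorm(1), 0.03, 1)
      sub_img <- img[e$rows, e$cols]
      sub_img[e$mask] <- tone
      img[e$rows, e$cols] <- sub_img
      sub_own <- owner[e$rows, e$cols]
      sub_own[e$mask] <- -1L
      owner[e$rows, e$cols] <- sub_own
    }

    visible <- tabulate(owner[owner > 0L], nbins = n)
    occ_frac <- 1 - visible / pmax(area, 1)
    gts <- if (n == 0L) empty_gt_df() else data.frame(
      image_id = image_id, cx = cx, cy = cy, r = r, class_id = 1L,
      occlusion_fraction = occ_frac, pixel_area = area,
      occlusion_tag = ifelse(occ_frac > 0.5, "severe", "slight"),
      illumination_tag = regime
    )
    list(image = img, gts = gts, illumination = regime)
  })
}

#' Derive a noisy detection list from ground truth
#'
#' Closes the loop between ground truth and detector output without a
#' trained network: each ground truth is dropped with probability
#' `miss_rate` or jittered (Gaussian center noise, log-normal radius
#' noise), and spurious detections are added at a Poisson rate of
#' `fp_rate` per ground truth, uniformly placed with radii resampled from
#' the ground-truth radius distribution. Under the `"noise"` confidence
#' model a kept detection's confidence decreases with its realized jitter
#' (so harder localizations score lower, yielding a non-degenerate
#' precision-recall curve), while spurious detections draw low-skewed
#' confidences; `"perfect"` assigns confidence 1 to all kept detections.
#'
#' @param gts Ground-truth data frame (`image_id`, `cx`, `cy`, `r`,
#'   optional `class_id`); may span several images.
#' @param sigma_center Center jitter s.d. in pixels (default 2).
#' @param sigma_logr Log-radius jitter s.d. (default 0.05).
#' @param miss_rate,fp_rate Planted miss and false-positive rates in
#'   `[0, 1]` (defaults 0.05).
#' @param conf_model `"noise"` (default) or `"perfect"`.
#' @param seed Integer seed.
#' @param image_size Image side length for placing spurious detections
#'   (default 416).
#' @return Detection data frame with columns `image_id`, `cx`, `cy`, `r`,
#'   `confidence`, `class_id` and a provenance column `source`
#'   (`"object"` or `"spurious"`).
#' @export
perturb_detections <- function(gts, sigma_center = 2, sigma_logr = 0.05,
                               miss_rate = 0.05, fp_rate = 0.05,
                               conf_model = c("noise", "perfect"),
                               seed = 0, image_size = 416) {
  conf_model <- match.arg(conf_model)
  if (miss_rate < 0 || miss_rate > 1 || fp_rate < 0 || fp_rate > 1)
    stop_input("miss_rate and fp_rate must lie in [0, 1]")
  if (!"image_id" %in% names(gts)) gts$image_id <- "scene"
  with_seed(seed, {
    n <- nrow(gts)
    keep <- stats::runif(n) >= miss_rate
    kept <- gts[keep, , drop = FALSE]
    m <- nrow(kept)
    dx <- stats::rnorm(m, 0, sigma_center)
    dy <- stats::rnorm(m, 0, sigma_center)
    dlr <- stats::rnorm(m, 0, sigma_logr)
    conf <- if (conf_model == "perfect") rep(1, m) else {
      zc <- sqrt(dx^2 + dy^2) / pmax(kept$r, 1)
      clamp(1 - 1.2 * zc - 1.5 * abs(dlr), 0.05, 1)
    }
    tp <- data.frame(
      image_id = kept$image_id,
      cx = kept$cx + dx, cy = kept$cy + dy, r = kept$r * exp(dlr),
      confidence = conf,
      class_id = if ("class_id" %in% names(kept)) kept$class_id else 1L,
      source = "object"
    )
    meanlog <- if (n > 0) mean(log(pmax(gts$r, 1))) else log(25)
    sdlog <- if (n > 1) stats::sd(log(pmax(gts$r, 1))) else 0.3
    fps <- lapply(split(seq_len(n), gts$image_id), function(ii) {
      k <- stats::rpois(1, fp_rate * length(ii))
      if (k == 0) return(NULL)
      data.frame(
        image_id = gts$image_id[ii[1]],
        cx = stats::runif(k, 0.08, 0.92) * image_size,
        cy = stats::runif(k, 0.08, 0.92) * image_size,
        r = clamp(stats::rlnorm(k, meanlog, max(sdlog, 1e-3)), 6, image_size / 3),
        confidence = 0.05 + 0.75 * stats::rbeta(k, 2, 5),
        class_id = 1L, source = "spurious"
      )
    })
    out <- rbind(tp, do.call(rbind, fps))
    rownames(out) <- NULL
    out
  })
}

#' Random scale/crop/flip augmentation
#'
#' Training-time augmentation for scenes: with equal probability the image
#' is passed through unchanged or scaled by a factor drawn uniformly from
#' `[1.15, 1.25]` and cropped back to the original size at a uniformly
#' random offset; afterwards it is flipped horizontally with probability
#' 0.5. Ground-truth circles are transformed accordingly (radii scaled,
#' centers shifted and mirrored); circles whose centers leave the crop are
#' dropped, circles with centers inside are kept even if partly cut.
#'
#' @param image Numeric image matrix (rows = y).
#' @param gts Ground-truth circle data frame.
#' @param seed Integer seed.
#' @param force Optional list overriding drawn parameters, any of `op`
#'   (`"identity"` or `"scale_crop"`), `factor`, `offx`, `offy` (crop
#'   offsets as fractions of the available slack; 0.5 = centered) and
#'   `flip`; used to make individual transforms reproducible.
#' @return A list with `image`, `gts` and `params` (the parameters
#'   applied).
#' @export
augment_scene <- function(image, gts, seed = 0, force = NULL) {
  H <- nrow(image); W <- ncol(image)
  pars <- with_seed(seed, list(
    op = if (stats::runif(1) < 0.5) "identity" else "scale_crop",
    factor = stats::runif(1, 1.15, 1.25),
    offx = stats::runif(1), offy = stats::runif(1),
    flip = stats::runif(1) < 0.5
  ))
  if (!is.null(force)) pars <- utils::modifyList(pars, force)
  img2 <- image; gts2 <- gts
  if (pars$op == "scale_crop") {
    f <- pars$factor
    if (f < 1) stop_input("scale factor must be >= 1 for scale-then-crop")
    ox <- pars$offx * (W * f - W)
    oy <- pars$offy * (H * f - H)
    sc <- clamp(ceiling(((seq_len(W) - 0.5) + ox) / f), 1, W)
    sr <- clamp(ceiling(((seq_len(H) - 0.5) + oy) / f), 1, H)
    img2 <- image[sr, sc, drop = FALSE]
    if (nrow(gts2)) {
      gts2$cx <- gts2$cx * f - ox
      gts2$cy <- gts2$cy * f - oy
      gts2$r <- gts2$r * f
      keep <- gts2$cx >= 0 & gts2$cx <= W & gts2$cy >= 0 & gts2$cy <= H
      gts2 <- gts2[keep, , drop = FALSE]
    }
  }
  if (isTRUE(pars$flip)) {
    img2 <- img2[, rev(seq_len(ncol(img2))), drop = FALSE]
    if (nrow(gts2)) gts2$cx <- W - gts2$cx
  }
  rownames(gts2) <- NULL
  list(image = img2, gts = gts2, params = pars)
}
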