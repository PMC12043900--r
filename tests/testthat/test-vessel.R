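draw_line_image <- function(n = 128, width = 6, value = 0.15, bg = 0.6,
                            vertical = FALSE) {
  img <- array(bg, dim = c(n, n, 3))
  half <- width / 2
  mid <- n / 2
  if (vertical) {
    img[(mid - half + 1):(mid + half), , ] <- value
  } else {
    img[, (mid - half + 1):(mid + half), ] <- value
  }
  img
}

test_that("vesselness is zero on a flat image", {
  roi <- as_test_roi(array(0.5, dim = c(96, 96, 3)))
  v <- compute_vesselness(roi)
  expect_true(all(v == 0))
})

line_scales <- c(1.5, 2.5, 3.5) # matched to the 4-10 px drawn widths

test_that("a straight dark line yields a ridge with a centred skeleton", {
  roi <- as_test_roi(draw_line_image(width = 6))
  v <- compute_vesselness(roi, scales = line_scales)
  vm <- binarize_and_skeletonize(v, min_size = 20)
  sk <- which(vm$skeleton, arr.ind = TRUE)
  expect_gt(nrow(sk), 50)
  # the centreline is the horizontal line y = 64 (pixel rows 64/65)
  inner <- sk[sk[, 1] > 20 & sk[, 1] < 108, , drop = FALSE]
  expect_true(all(abs(inner[, 2] - 64.5) <= 1.5))
})

test_that("vesselness commutes with 90-degree rotation", {
  sc <- cached_scene(2)
  roi <- normalize_enhance(extract_roi(sc$image))
  n <- dim(roi$image)[1]
  m <- min(n, dim(roi$image)[2])
  img <- roi$image[1:m, 1:m, , drop = FALSE]
  mask <- roi$mask[1:m, 1:m]
  r0 <- as_test_roi(img)
  r0$mask <- mask
  rot_img <- aperm(img[, m:1, , drop = FALSE], c(2, 1, 3))
  r90 <- as_test_roi(rot_img)
  r90$mask <- t(mask[, m:1])
  v0 <- compute_vesselness(r0)
  v90 <- compute_vesselness(r90)
  back <- t(v90)[, m:1]
  expect_lt(max(abs(v0 - back)), 1e-6)
})

test_that("width estimation tracks drawn widths and their ordering", {
  roi <- as_test_roi(draw_line_image(width = 8))
  vm <- binarize_and_skeletonize(compute_vesselness(roi, scales = line_scales),
                                 min_size = 20)
  wd <- vm$width_px[vm$skeleton]
  expect_gte(stats::median(wd), 7)
  expect_lte(stats::median(wd), 9)

  # two parallel vessels, widths 10 and 4: ordering preserved
  img <- array(0.6, dim = c(128, 128, 3))
  img[, 30:39, ] <- 0.15
  img[, 90:93, ] <- 0.15
  vm2 <- binarize_and_skeletonize(
    compute_vesselness(as_test_roi(img), scales = line_scales),
    min_size = 20
  )
  sk <- which(vm2$skeleton, arr.ind = TRUE)
  w_thick <- stats::median(vm2$width_px[vm2$skeleton & row(vm2$skeleton) > 0 &
                                          col(vm2$skeleton) %in% 30:39])
  w_thin <- stats::median(vm2$width_px[vm2$skeleton & col(vm2$skeleton) %in% 90:93])
  expect_gt(w_thick, w_thin)
})

test_that("empty vesselness yields an empty flagged map", {
  vm <- binarize_and_skeletonize(matrix(0, 64, 64))
  expect_true("empty_vessels" %in% vm$flags)
  expect_false(any(vm$mask))
  expect_false(any(vm$skeleton))
})

test_that("skeleton and width invariants hold on a full scene", {
  m <- cached_measurement(1)
  vm <- m$artifacts$vessel_map
  expect_true(all(vm$mask[vm$skeleton])) # skeleton subset of mask
  expect_true(all(vm$width_px[vm$skeleton] > 0))
  expect_true(all(vm$width_px[!vm$skeleton] == 0))
})

test_that("arcade tracing picks the widest crossings and reaches 3 PD", {
  sc <- cached_scene(1)
  m <- cached_measurement(1)
  arcades <- m$artifacts$arcades
  for (side in c("superior", "inferior")) {
    widest <- arcades[[side]][[1]]
    expect_true(widest$reaches_3pd)
    # traced path stays close to the true Bezier polyline (Hausdorff)
    tb <- sc$truth$arcade_beziers[[side]]
    off <- c(m$artifacts$roi$bbox[1], m$artifacts$roi$bbox[2])
    dense <- bezier_point(tb$p0 - off, tb$p1 - off, tb$p2 - off,
                          seq(0, 1, length.out = 2000))
    d <- vapply(seq_len(nrow(widest$points_px)), function(i) {
      min(sqrt((dense[, 1] - widest$points_px[i, 1])^2 +
                 (dense[, 2] - widest$points_px[i, 2])^2))
    }, numeric(1))
    expect_lt(max(d), 3)
    # radial distance non-decreasing after smoothing
    r <- sqrt(rowSums((widest$points_px -
                         matrix(m$O, nrow(widest$points_px), 2,
                                byrow = TRUE))^2))
    rs <- stats::filter(r, rep(1 / 5, 5), sides = 2)
    rs <- rs[!is.na(rs)]
    expect_true(all(diff(rs) > -1))
  }
})

test_that("a side with no vessels raises an arcade-not-found error", {
  acp <- arcade_geometry()
  acp$inferior <- NULL
  sc <- generate_fundus_scene(
    scene_params(seed = 5, arcade_control_points = acp,
                 n_distractor_vessels = 0L)
  )
  roi <- normalize_enhance(extract_roi(sc$image))
  vess <- compute_vesselness(roi)
  disc <- segment_disc(roi, vesselness = vess)
  vmap <- binarize_and_skeletonize(vess)
  err <- tryCatch(trace_arcades(vmap, disc), condition = function(e) e)
  expect_s3_class(err, "vaangle_arcade_not_found")
  expect_true("inferior" %in% err$side)
})
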