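fake_path <- function(points, side = "inferior", reaches = TRUE) {
  structure(list(side = side, points_px = points,
                 widths_px = rep(5, nrow(points)), mean_width_px = 5,
                 reaches_3pd = reaches),
            class = "arcade_path")
}

fake_disc <- function(O = c(0, 0), pd = 50) {
  structure(list(center_px = O, pd_px = pd, boundary_px = NULL,
                 bbox = c(O[1] - pd, O[2] - pd, O[1] + pd, O[2] + pd),
                 confidence = 1),
            class = "disc_geometry")
}

test_that("point B is the midpoint of the two 3 PD crossings (closed form)", {
  disc <- fake_disc(O = c(0, 0), pd = 50)
  # straight vessels at -30 and -60 degrees below the horizontal
  ray <- function(deg) {
    th <- deg * pi / 180
    t_ <- seq(1, 200, length.out = 80)
    cbind(t_ * cos(th), t_ * sin(th))
  }
  paths <- list(fake_path(ray(30)), fake_path(ray(60)))
  B <- locate_point_B(paths, disc)
  expected <- (150 * c(cos(pi / 6), sin(pi / 6)) +
                 150 * c(cos(pi / 3), sin(pi / 3))) / 2
  expect_equal(B, expected, tolerance = 1e-6)

  # identical twin vessels: B on the shared crossing
  twins <- list(fake_path(ray(45)), fake_path(ray(45)))
  expect_equal(locate_point_B(twins, disc),
               150 * c(cos(pi / 4), sin(pi / 4)), tolerance = 1e-6)

  # a trace that stops short of 3 PD fails with the arcade flag
  short <- fake_path(ray(45)[1:10, ], reaches = FALSE)
  expect_error(locate_point_B(list(short), disc),
               class = "vaangle_keypoint_failure")
})

test_that("point C mirrors B and supports the vertical-line rule", {
  disc <- fake_disc(O = c(0, 0), pd = 50)
  ray <- function(deg) {
    th <- deg * pi / 180
    t_ <- seq(1, 200, length.out = 80)
    cbind(t_ * cos(th), -t_ * sin(th))
  }
  paths <- list(fake_path(ray(30), side = "superior"),
                fake_path(ray(60), side = "superior"))
  C <- locate_point_C(paths, disc)
  expected <- (150 * c(cos(pi / 6), -sin(pi / 6)) +
                 150 * c(cos(pi / 3), -sin(pi / 3))) / 2
  expect_equal(C, expected, tolerance = 1e-6)

  # vertical rule: crossing of x = O_x; build a path crossing x = 0
  horiz <- cbind(seq(-50, 50, length.out = 41), rep(-80, 41))
  Cv <- locate_point_C(list(fake_path(horiz, side = "superior")), disc,
                       rule = "vertical")
  expect_equal(Cv, c(0, -80), tolerance = 1e-9)
})

test_that("Bezier fitting recovers exact curves and degenerate lines", {
  p0 <- c(0, 0)
  p1 <- c(50, 80)
  p2 <- c(160, 120)
  pts <- bezier_point(p0, p1, p2, seq(0.05, 0.95, length.out = 20))
  fit <- fit_bezier_arc(pts, p0, p2)
  expect_lt(sqrt(sum((fit$p1 - p1)^2)), 1e-6)

  # straight path: the fitted curve is the segment
  line_pts <- bezier_point(c(0, 0), c(100, 0), c(200, 0),
                           seq(0.1, 0.9, length.out = 10))
  lf <- fit_bezier_arc(line_pts, c(0, 0), c(200, 0))
  dev <- bezier_point(lf$p0, lf$p1, lf$p2, seq(0, 1, 0.01))[, 2]
  expect_lt(max(abs(dev)), 1e-9)

  # a symmetric bump displaces the control point to the bump side
  t_ <- seq(0.05, 0.95, length.out = 40)
  bump <- cbind(200 * t_, 10 * sin(pi * t_)) # bump toward +y
  bf <- fit_bezier_arc(bump, c(0, 0), c(200, 0))
  expect_gt(bf$p1[2], 0)

  expect_error(fit_bezier_arc(pts[1:2, ], p0, p2),
               class = "vaangle_invalid_params")
})

test_that("full-scene measurement matches the analytic ground truth", {
  for (s in 1:3) {
    sc <- cached_scene(s)
    m <- cached_measurement(s)
    expect_length(m$qc_flags, 0)
    expect_lt(abs(m$vaa_1pd_deg - sc$truth$true_vaa_1pd_deg), 2)
    expect_lt(abs(m$vaa_2pd_deg - sc$truth$true_vaa_2pd_deg), 2)
    expect_lt(m$vaa_2pd_deg, m$vaa_1pd_deg) # temporal convergence
    # crossing points sit on their circles
    for (nm in c("D", "E")) {
      expect_equal(sqrt(sum((m[[nm]] - m$O)^2)), 2 * m$pd_px,
                   tolerance = 0.5 / (2 * m$pd_px))
    }
    for (nm in c("F", "G")) {
      expect_equal(sqrt(sum((m[[nm]] - m$O)^2)), m$pd_px,
                   tolerance = 0.5 / m$pd_px)
    }
    # sides: D and F inferior (larger y than O), E and G superior
    expect_gt(m$D[2], m$O[2])
    expect_gt(m$F[2], m$O[2])
    expect_lt(m$E[2], m$O[2])
    expect_lt(m$G[2], m$O[2])
  }
})

test_that("a missing arcade yields flagged, absent angles", {
  acp <- arcade_geometry()
  acp$superior <- NULL
  sc <- generate_fundus_scene(scene_params(seed = 5,
                                           arcade_control_points = acp))
  m <- measure_vaa(sc, keep_artifacts = FALSE)
  expect_true("arcade_missing" %in% m$qc_flags)
  expect_true(is.na(m$vaa_1pd_deg))
  expect_true(is.na(m$vaa_2pd_deg))
})

test_that("measurements tidy into one-row tibbles", {
  m <- cached_measurement(1)
  tb <- tidy(m)
  expect_s3_class(tb, "tbl_df")
  expect_equal(nrow(tb), 1)
  expect_true(all(c("vaa_1pd_deg", "vaa_2pd_deg", "pd_px", "o_x", "b_y",
                    "qc_flags") %in% names(tb)))
  tb2 <- as_tibble(m)
  expect_equal(tb2$vaa_1pd_deg, m$vaa_1pd_deg)
})

test_that("autoplot builds annotated overlays without error", {
  m <- cached_measurement(1)
  sc <- cached_scene(1)
  p <- autoplot(m, image = sc)
  expect_s3_class(p, "ggplot")
  p2 <- autoplot(sc)
  expect_s3_class(p2, "ggplot")
})
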