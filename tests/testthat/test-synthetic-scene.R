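test_that("scene parameter validation rejects impossible arcades", {
  # endpoint inside the 3 PD circle
  acp <- arcade_geometry(end_dist_pd = 2.0)
  expect_error(scene_params(arcade_control_points = acp),
               class = "vaangle_invalid_params")
  # both arcades along the same ray: zero included angle
  O <- c(0.72, 0.5) * 512
  ray <- rbind(O, O + c(-150, 0), O + c(-300, 0))
  expect_error(
    scene_params(arcade_control_points = list(superior = ray, inferior = ray)),
    class = "vaangle_invalid_params"
  )
})

test_that("straight-ray arcades subtend the same angle at every radius", {
  O <- c(0.72, 0.5) * 512
  ray <- function(th) rbind(O, O + 150 * c(cos(th), sin(th)),
                            O + 300 * c(cos(th), sin(th)))
  acp <- list(superior = ray(pi + pi / 4), inferior = ray(pi - pi / 4))
  sc <- generate_fundus_scene(
    scene_params(noise_sigma = 0, arcade_control_points = acp, seed = 3)
  )
  expect_equal(sc$truth$true_vaa_1pd_deg, 90, tolerance = 1e-9)
  expect_equal(sc$truth$true_vaa_2pd_deg, 90, tolerance = 1e-9)
})

test_that("ground-truth angles match the dense-sampling oracle", {
  sc <- cached_scene(1)
  arcs <- sc$truth$arcade_beziers
  O <- sc$truth$disc_center_px
  for (r in c(sc$truth$pd_px, 2 * sc$truth$pd_px)) {
    p_sup <- oracle_circle_crossing(arcs$superior, O, r)
    p_inf <- oracle_circle_crossing(arcs$inferior, O, r)
    ref <- angle_at_O(O, p_sup, p_inf)
    got <- if (r == sc$truth$pd_px) sc$truth$true_vaa_1pd_deg else sc$truth$true_vaa_2pd_deg
    expect_lt(abs(got - ref), 1e-6)
  }
  # temporally converging arcades: narrower at 2 PD than at 1 PD
  expect_lt(sc$truth$true_vaa_2pd_deg, sc$truth$true_vaa_1pd_deg)
  expect_gt(sc$truth$true_vaa_2pd_deg, 0)
  expect_lt(sc$truth$true_vaa_1pd_deg, 360)
})

test_that("scene generation is bit-identical under a fixed seed", {
  a <- generate_fundus_scene(scene_params(seed = 9))
  b <- generate_fundus_scene(scene_params(seed = 9))
  expect_identical(EBImage::imageData(a$image), EBImage::imageData(b$image))
  c_ <- generate_fundus_scene(scene_params(seed = 10))
  expect_false(identical(EBImage::imageData(a$image),
                         EBImage::imageData(c_$image)))
})

test_that("the rendered scene has the stated photometric structure", {
  sc <- cached_scene(1)
  img <- EBImage::imageData(sc$image)
  n <- dim(img)[1]
  O <- sc$truth$disc_center_px
  at <- function(p) img[round(p[1] + 0.5), round(p[2] + 0.5), ]
  corner <- img[2, 2, ]
  expect_true(all(corner == 0)) # black surround
  bg_probe <- at(O + c(0, 150))
  disc_probe <- at(O)
  # the disc centre carries vessels; probe a clear disc spot instead
  disc_clear <- at(O + c(10, 10) / sqrt(2))
  expect_true(all(disc_clear > bg_probe))
  vessel_probe <- at(drop(bezier_point(sc$truth$arcade_beziers$superior$p0,
                                       sc$truth$arcade_beziers$superior$p1,
                                       sc$truth$arcade_beziers$superior$p2,
                                       0.5)))
  expect_true(all(vessel_probe < bg_probe))
})

test_that("laterality mirrors the scene geometry", {
  right <- scene_params(seed = 2, laterality = "right")
  left <- scene_params(seed = 2, laterality = "left")
  expect_gt(right$disc_center_frac[1], 0.5)
  expect_lt(left$disc_center_frac[1], 0.5)
  # arcades open temporally: endpoints on the macular side of the disc
  expect_lt(right$arcade_control_points$superior[3, 1],
            right$disc_center_frac[1] * 512)
  expect_gt(left$arcade_control_points$superior[3, 1],
            left$disc_center_frac[1] * 512)
})

test_that("scenes round-trip to PNG with a JSON ground-truth sidecar", {
  sc <- cached_scene(1)
  png <- tempfile(fileext = ".png")
  write_scene(sc, png)
  json <- sub("\\.png$", ".json", png)
  expect_true(file.exists(png) && file.exists(json))
  tr <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_equal(tr$pd_px, sc$truth$pd_px)
  expect_equal(tr$true_vaa_1pd_deg, sc$truth$true_vaa_1pd_deg,
               tolerance = 1e-12)
  img <- EBImage::readImage(png)
  expect_equal(dim(img)[1:2], c(512L, 512L))
  unlink(c(png, json))
})
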