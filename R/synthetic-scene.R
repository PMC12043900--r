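# Synthetic fundus scenes with analytic ground truth.
#
# A scene emulates the content of a posterior-pole fundus photograph that
# the measurement pipeline relies on: a black surround outside a circular
# camera aperture, an orange background with mild vignetting, a bright
# circular optic disc on the nasal side, and two dark arcade vessels that
# leave the disc centre and curve temporally as quadratic Bezier curves.
# The true arcade Beziers are kept alongside the raster so the arcade
# angle at any radius is known analytically, independent of rendering.

#' Parameters of a synthetic fundus scene
#'
#' Defaults describe a right-eye posterior-pole photograph: disc on the
#' nasal (right) side of the image, arcades opening temporally, with the
#' default arcade geometry chosen so the true angles fall near the middle
#' of the range observed in highly myopic eyes (about 128 degrees at 1 PD
#' and 110 degrees at 2 PD).
#'
#' @param image_size_px Square image side, pixels.
#' @param aperture_radius_frac Camera-aperture radius as a fraction of the
#'   image half-width.
#' @param disc_center_frac Disc centre as (x, y) fractions of the image
#'   size; `NULL` picks the lateralized default.
#' @param disc_radius_px Optic-disc radius in pixels (papillary diameter
#'   is twice this). Zero renders no disc (for failure-path testing).
#' @param arcade_control_points `NULL` for the default geometry, or a list
#'   with elements `superior` and `inferior`, each a 3 x 2 matrix of rows
#'   P0 (= disc centre), P1 (control), P2 (endpoint), pixels.
#' @param arcade_width_px Full vessel width of the arcades, pixels.
#' @param n_distractor_vessels Number of thin non-arcade vessels.
#' @param noise_sigma Additive Gaussian noise SD in 8-bit gray levels.
#' @param vignette_strength Peripheral darkening factor in `[0, 1)`.
#' @param laterality `"right"` or `"left"`.
#' @param hard_mode If `TRUE`, distractor vessels may cross the 1-3 PD
#'   measurement annulus in the arcade sectors (robustness testing); by
#'   default they are confined to the nasal half.
#' @param seed Integer seed; the scene is bit-identical for a fixed seed.
#' @return A list of class `scene_params`.
#' @export
scene_params <- function(image_size_px = 512L,
                         aperture_radius_frac = 0.95,
                         disc_center_frac = NULL,
                         disc_radius_px = 32,
                         arcade_control_points = NULL,
                         arcade_width_px = 7,
                         n_distractor_vessels = 6L,
                         noise_sigma = 5,
                         vignette_strength = 0.15,
                         laterality = c("right", "left"),
                         hard_mode = FALSE,
                         seed = 1L) {
  laterality <- match.arg(laterality)
  if (is.null(disc_center_frac)) {
    disc_center_frac <- if (laterality == "right") c(0.72, 0.5) else c(0.28, 0.5)
  }
  p <- structure(list(
    image_size_px = as.integer(image_size_px),
    aperture_radius_frac = aperture_radius_frac,
    disc_center_frac = disc_center_frac,
    disc_radius_px = disc_radius_px,
    arcade_control_points = arcade_control_points,
    arcade_width_px = arcade_width_px,
    n_distractor_vessels = as.integer(n_distractor_vessels),
    noise_sigma = noise_sigma,
    vignette_strength = vignette_strength,
    laterality = laterality,
    hard_mode = isTRUE(hard_mode),
    seed = as.integer(seed)
  ), class = "scene_params")
  p$arcade_control_points <- .default_arcades(p)
  .validate_scene_params(p)
  p
}

#' Construct arcade control points from polar geometry
#'
#' Builds the 3 x 2 control-point matrices of both arcade Beziers from
#' half-angles (measured from the temporal horizontal through the disc
#' centre) and radial distances in papillary diameters. Shrinking the
#' half-angles "pinches" the arcades and reduces the true angle at every
#' radius.
#'
#' @param image_size_px,disc_center_frac,disc_radius_px,laterality As in
#'   [scene_params()].
#' @param ctrl_half_angle_deg,ctrl_dist_pd Control-point half-angle
#'   (degrees) and distance (papillary diameters); defaults 75 and 1.5.
#' @param end_half_angle_deg,end_dist_pd Endpoint half-angle and
#'   distance; defaults 45 and 3.3 (beyond the 3 PD circle).
#' @return A list with 3 x 2 matrices `superior` and `inferior`.
#' @export
arcade_geometry <- function(image_size_px = 512L,
                            disc_center_frac = c(0.72, 0.5),
                            disc_radius_px = 32,
                            ctrl_half_angle_deg = 75, ctrl_dist_pd = 1.5,
                            end_half_angle_deg = 45, end_dist_pd = 3.3,
                            laterality = c("right", "left")) {
  laterality <- match.arg(laterality)
  O <- disc_center_frac * image_size_px
  pd <- 2 * disc_radius_px
  s_temporal <- if (laterality == "right") -1 else 1
  arm <- function(sgn_y) {
    th1 <- ctrl_half_angle_deg * pi / 180
    th2 <- end_half_angle_deg * pi / 180
    p1 <- O + c(s_temporal * ctrl_dist_pd * pd * cos(th1),
                sgn_y * ctrl_dist_pd * pd * sin(th1))
    p2 <- O + c(s_temporal * end_dist_pd * pd * cos(th2),
                sgn_y * end_dist_pd * pd * sin(th2))
    rbind(O, p1, p2)
  }
  list(superior = arm(-1), inferior = arm(+1))
}

# default arcade geometry for a scene (either side may be set to NULL by
# the caller to render a scene missing that arcade)
.default_arcades <- function(p) {
  if (!is.null(p$arcade_control_points)) return(p$arcade_control_points)
  if (p$disc_radius_px <= 0) return(NULL)
  arcade_geometry(p$image_size_px, p$disc_center_frac, p$disc_radius_px,
                  laterality = p$laterality)
}

.validate_scene_params <- function(p) {
  if (p$image_size_px < 64) {
    stop_vaangle("image_size_px must be at least 64", "invalid_params")
  }
  if (p$disc_radius_px < 0) {
    stop_vaangle("disc_radius_px must be non-negative", "invalid_params")
  }
  acp <- p$arcade_control_points
  if (p$disc_radius_px > 0 && !is.null(acp)) {
    O <- p$disc_center_frac * p$image_size_px
    pd <- 2 * p$disc_radius_px
    sides <- Filter(function(s) !is.null(acp[[s]]), c("superior", "inferior"))
    for (side in sides) {
      m <- acp[[side]]
      if (!is.matrix(m) || !all(dim(m) == c(3, 2))) {
        stop_vaangle("each arcade needs a 3 x 2 control-point matrix",
                     "invalid_params")
      }
      if (sqrt(sum((m[3, ] - O)^2)) < 3 * pd) {
        stop_vaangle(
          "arcade endpoint lies inside the 3 PD circle; it must cross it",
          "invalid_params"
        )
      }
    }
    if (length(sides) == 2) {
      # degenerate: both arcades along the same ray from O
      u <- acp$superior[3, ] - O
      v <- acp$inferior[3, ] - O
      ang <- atan2(abs(u[1] * v[2] - u[2] * v[1]), sum(u * v)) * 180 / pi
      if (ang < 1) {
        stop_vaangle("arcades are collinear from the disc centre (zero angle)",
                     "invalid_params")
      }
    }
  }
  invisible(p)
}

#' Generate a synthetic fundus scene with analytic ground truth
#'
#' Renders the scene described by [scene_params()] and returns both the
#' RGB raster and its ground truth: the disc centre, the papillary
#' diameter, the true arcade Beziers and the true arcade angles at 1 and
#' 2 PD (computed from the Beziers with [analytic_vaa()], never from the
#' rendered pixels).
#'
#' @param params A [scene_params()] object.
#' @return A list of class `fundus_scene` with elements `image` (an
#'   `EBImage::Image`, colour, values in `[0, 1]`) and `truth` (list with
#'   `disc_center_px`, `pd_px`, `arcade_beziers`, `true_vaa_1pd_deg`,
#'   `true_vaa_2pd_deg`).
#' @examples
#' sc <- generate_fundus_scene(scene_params(seed = 7))
#' sc$truth$true_vaa_1pd_deg
#' @export
generate_fundus_scene <- function(params = scene_params()) {
  if (!inherits(params, "scene_params")) {
    params <- do.call(scene_params, params)
  }
  .validate_scene_params(params)
  rs <- .preserve_rng()
  on.exit(.restore_rng(rs), add = TRUE)
  set.seed(params$seed)

  n <- params$image_size_px
  O <- params$disc_center_frac * n
  pd <- 2 * params$disc_radius_px
  xs <- matrix(rep(seq_len(n) - 0.5, n), n, n)
  ys <- matrix(rep(seq_len(n) - 0.5, each = n), n, n)
  ap_c <- c(n, n) / 2
  ap_r <- params$aperture_radius_frac * n / 2
  r_ap <- sqrt((xs - ap_c[1])^2 + (ys - ap_c[2])^2)
  aperture <- r_ap <= ap_r

  bg <- c(0.82, 0.45, 0.25)
  disc_col <- c(0.97, 0.86, 0.62)
  vessel_col <- c(0.45, 0.12, 0.10)

  # layer masks
  disc_mask <- if (params$disc_radius_px > 0) {
    sqrt((xs - O[1])^2 + (ys - O[2])^2) <= params$disc_radius_px
  } else {
    matrix(FALSE, n, n)
  }

  vessel_mask <- matrix(FALSE, n, n)
  arcs <- NULL
  if (!is.null(params$arcade_control_points)) {
    acp <- params$arcade_control_points
    arcs <- list()
    for (side in c("superior", "inferior")) {
      if (is.null(acp[[side]])) next
      arcs[[side]] <- bezier_arc(acp[[side]][1, ], acp[[side]][2, ],
                                 acp[[side]][3, ], side = side)
      vessel_mask <- vessel_mask |
        .stamp_curve(acp[[side]][1, ], acp[[side]][2, ], acp[[side]][3, ],
                     n, params$arcade_width_px)
    }
    if (length(arcs) == 0) arcs <- NULL
  }

  # distractor vessels: thin curves kept out of the temporal measurement
  # annulus unless hard_mode
  if (params$n_distractor_vessels > 0 && pd > 0) {
    s_temporal <- if (params$laterality == "right") -1 else 1
    for (i in seq_len(params$n_distractor_vessels)) {
      if (params$hard_mode) {
        th <- stats::runif(1, 0, 2 * pi)
      } else {
        # nasal half: directions within +/- 60 deg of the anti-temporal axis
        base <- if (s_temporal < 0) 0 else pi
        th <- base + stats::runif(1, -pi / 3, pi / 3)
      }
      r0 <- stats::runif(1, 1.3, 1.6) * pd # clear of the selection ring
      len <- r0 + stats::runif(1, 0.8, 1.6) * pd
      p0 <- O + r0 * c(cos(th), sin(th))
      p2 <- O + len * c(cos(th), sin(th))
      mid <- (p0 + p2) / 2
      perp <- c(-sin(th), cos(th)) * stats::runif(1, -0.3, 0.3) * len
      d_mask <- .stamp_curve(p0, mid + perp, p2, n, 3)
      vessel_mask <- vessel_mask | d_mask
    }
  }

  img <- array(0, dim = c(n, n, 3))
  vig <- 1 - params$vignette_strength * (r_ap / ap_r)^2
  for (ch in 1:3) {
    plane <- matrix(bg[ch], n, n)
    plane[disc_mask] <- disc_col[ch]
    plane[vessel_mask] <- vessel_col[ch]
    plane <- plane * vig
    img[, , ch] <- plane
  }

  # mild optical blur for sub-pixel edges, then sensor noise
  im <- EBImage::Image(img, colormode = "Color")
  im <- EBImage::gblur(im, sigma = 0.7)
  img <- EBImage::imageData(im)
  if (params$noise_sigma > 0) {
    img <- img + array(stats::rnorm(length(img), 0, params$noise_sigma / 255),
                       dim = dim(img))
  }
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[!aperture] <- 0
    img[, , ch] <- plane
  }
  img[img < 0] <- 0
  img[img > 1] <- 1

  truth <- list(disc_center_px = O, pd_px = pd, arcade_beziers = arcs,
                true_vaa_1pd_deg = NA_real_, true_vaa_2pd_deg = NA_real_)
  if (!is.null(arcs) && length(arcs) == 2 && pd > 0) {
    truth$true_vaa_1pd_deg <- analytic_vaa(unname(arcs), O, pd)
    truth$true_vaa_2pd_deg <- analytic_vaa(unname(arcs), O, 2 * pd)
  }

  structure(list(image = EBImage::Image(img, colormode = "Color"),
                 truth = truth, params = params),
            class = "fundus_scene")
}

#' @export
print.fundus_scene <- function(x, ...) {
  cat(sprintf(
    "<fundus_scene %dpx %s eye> PD=%.0fpx true VAA(1PD)=%.2f deg VAA(2PD)=%.2f deg\n",
    x$params$image_size_px, x$params$laterality, x$truth$pd_px,
    x$truth$true_vaa_1pd_deg, x$truth$true_vaa_2pd_deg))
  invisible(x)
}

# rasterize a quadratic Bezier as a stroke of the given full width:
# dense centreline samples, then binary dilation with a disc brush
.stamp_curve <- function(p0, p1, p2, n, width_px) {
  tt <- seq(0, 1, length.out = 4L * n)
  pts <- bezier_point(p0, p1, p2, tt)
  ix <- round(pts[, 1] + 0.5)
  iy <- round(pts[, 2] + 0.5)
  keep <- ix >= 1 & ix <= n & iy >= 1 & iy <= n
  m <- matrix(0L, n, n)
  m[cbind(ix[keep], iy[keep])] <- 1L
  if (width_px > 1) {
    brush_size <- 2L * floor(width_px / 2) + 1L
    m <- EBImage::imageData(EBImage::dilate(m, EBImage::makeBrush(brush_size, "disc")))
  }
  m > 0
}

#' Write a scene to disk as PNG plus a JSON ground-truth sidecar
#'
#' @param scene A [generate_fundus_scene()] result.
#' @param png_path Output PNG path.
#' @param json_path Output JSON path; default replaces the extension.
#' @return Invisibly, the two paths.
#' @export
write_scene <- function(scene, png_path,
                        json_path = sub("\\.png$", ".json", png_path)) {
  stopifnot(inherits(scene, "fundus_scene"))
  EBImage::writeImage(scene$image, png_path)
  truth <- scene$truth
  tr <- list(
    disc_center_px = truth$disc_center_px,
    pd_px = truth$pd_px,
    true_vaa_1pd_deg = truth$true_vaa_1pd_deg,
    true_vaa_2pd_deg = truth$true_vaa_2pd_deg,
    arcade_beziers = lapply(truth$arcade_beziers, function(a) {
      list(p0 = a$p0, p1 = a$p1, p2 = a$p2, side = a$side)
    })
  )
  jsonlite::write_json(tr, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(png = png_path, json = json_path))
}
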