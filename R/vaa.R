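# The method core: key points O, B, C; quadratic Bezier fitting of the
# arcades; crossings D, E (2 PD circle) and F, G (1 PD circle); and the
# two arcade angles, VAA(1PD) = angle FOG and VAA(2PD) = angle DOE.

#' Locate key point B (inferior) or C (superior)
#'
#' B is the midpoint of the crossings of the two inferior arcade vessels
#' (the arteriovenous pair) with the circle of radius 3 papillary
#' diameters centred at O. C is its superior counterpart; under the
#' `"vertical"` rule C is instead the midpoint of the pair where the
#' vertical line through O crosses it.
#'
#' @param paths A list of 1-2 [arcade_path][trace_arcades()] objects of
#'   one side.
#' @param disc A [segment_disc()] result.
#' @param radius_pd Crossing-circle radius in papillary diameters
#'   (default 3).
#' @return The key point (length-2 numeric).
#' @export
locate_point_B <- function(paths, disc, radius_pd = 3) {
  .locate_keypoint(paths, disc, radius_pd, rule = "symmetric")
}

#' @rdname locate_point_B
#' @param rule `"symmetric"` (3 PD-crossing midpoint, default) or
#'   `"vertical"` (vertical line through O).
#' @export
locate_point_C <- function(paths, disc, radius_pd = 3,
                           rule = c("symmetric", "vertical")) {
  rule <- match.arg(rule)
  .locate_keypoint(paths, disc, radius_pd, rule = rule)
}

.locate_keypoint <- function(paths, disc, radius_pd, rule) {
  stopifnot(length(paths) >= 1)
  O <- disc$center_px
  r3 <- radius_pd * disc$pd_px
  side <- paths[[1]]$side
  crossings <- lapply(paths, function(p) {
    if (rule == "symmetric") {
      if (!isTRUE(p$reaches_3pd)) {
        stop_vaangle(
          sprintf("%s arcade trace does not reach the %g PD circle",
                  side, radius_pd),
          "keypoint_failure", side = side
        )
      }
      polyline_circle_crossing(p$points_px, O, r3)
    } else {
      .polyline_vertical_crossing(p$points_px, O)
    }
  })
  if (length(crossings) == 1) return(crossings[[1]])
  (crossings[[1]] + crossings[[2]]) / 2
}

# first crossing of a polyline with the vertical line x = O_x
.polyline_vertical_crossing <- function(points, O) {
  dx <- points[, 1] - O[1]
  n <- nrow(points)
  seg <- which(dx[-n] * dx[-1] <= 0 & !(dx[-n] == 0 & dx[-1] == 0))
  if (length(seg) == 0) {
    if (any(dx == 0)) return(points[which(dx == 0)[1], ])
    stop_vaangle("trace does not cross the vertical line through O",
                 "keypoint_failure")
  }
  i <- seg[1]
  s <- dx[i] / (dx[i] - dx[i + 1])
  points[i, ] + s * (points[i + 1, ] - points[i, ])
}

#' Fit a quadratic Bezier arc to a traced arcade
#'
#' Endpoints are fixed (`P0 = O`, `P2 =` the key point); the single
#' control point is the closed-form linear least squares solution against
#' the path points under chord-length parameterization (t from the
#' cumulative arc length of the polyline O -> path -> endpoint).
#'
#' @param path An [arcade_path][trace_arcades()] or an n x 2 point matrix.
#' @param O Disc centre (curve start).
#' @param endpoint Curve end (key point B or C).
#' @return A [bezier_arc()] with an extra `rms_px` residual field.
#' @export
fit_bezier_arc <- function(path, O, endpoint) {
  pts <- if (inherits(path, "arcade_path")) path$points_px else path
  side <- if (inherits(path, "arcade_path")) path$side else NA_character_
  stopifnot(is.matrix(pts), ncol(pts) == 2)
  if (nrow(pts) < 3) {
    stop_vaangle("need at least 3 path points to fit the arc", "invalid_params")
  }
  poly <- rbind(O, pts, endpoint)
  seg <- sqrt(rowSums((poly[-1, , drop = FALSE] -
                         poly[-nrow(poly), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0) {
    stop_vaangle("degenerate path: zero total length", "invalid_params")
  }
  t_all <- cum / total
  ti <- t_all[2:(nrow(poly) - 1)] # parameters of the path points

  solve_p1 <- function(ti) {
    a <- 2 * ti * (1 - ti)
    keep <- a > 1e-12 # points coincident with an endpoint carry no information
    if (!any(keep)) return((O + endpoint) / 2)
    ak <- a[keep]
    res_x <- pts[keep, 1] - (1 - ti[keep])^2 * O[1] - ti[keep]^2 * endpoint[1]
    res_y <- pts[keep, 2] - (1 - ti[keep])^2 * O[2] - ti[keep]^2 * endpoint[2]
    denom <- sum(ak^2)
    c(sum(ak * res_x) / denom, sum(ak * res_y) / denom)
  }
  p1 <- solve_p1(ti)
  # chord-length t only approximates the curve parameter, which biases
  # the linear solution; alternate exact orthogonal projection (dense
  # bracketing + Newton on (P(t)-Q).P'(t) = 0) with the linear solve
  # until the control point is stationary
  project <- function(p1v) {
    ts <- seq(0, 1, length.out = 257L)
    curve <- bezier_point(O, p1v, endpoint, ts)
    d2 <- outer(pts[, 1], curve[, 1], `-`)^2 +
      outer(pts[, 2], curve[, 2], `-`)^2
    t_i <- ts[max.col(-d2, ties.method = "first")]
    for (nz in seq_len(8L)) {
      pc <- bezier_point(O, p1v, endpoint, t_i)
      dx <- pc[, 1] - pts[, 1]
      dy <- pc[, 2] - pts[, 2]
      d1x <- 2 * (1 - t_i) * (p1v[1] - O[1]) + 2 * t_i * (endpoint[1] - p1v[1])
      d1y <- 2 * (1 - t_i) * (p1v[2] - O[2]) + 2 * t_i * (endpoint[2] - p1v[2])
      d2x <- 2 * (endpoint[1] - 2 * p1v[1] + O[1])
      d2y <- 2 * (endpoint[2] - 2 * p1v[2] + O[2])
      g <- dx * d1x + dy * d1y
      gp <- d1x^2 + d1y^2 + dx * d2x + dy * d2y
      step <- ifelse(abs(gp) > 1e-12, g / gp, 0)
      t_i <- pmin(pmax(t_i - step, 0), 1)
      if (max(abs(step)) < 1e-12) break
    }
    t_i
  }
  objective <- function(p1v) {
    ti <- project(p1v)
    fitted <- bezier_point(O, p1v, endpoint, ti)
    mean(rowSums((fitted - pts)^2))
  }
  # the chord-length start can sit in a shallow side valley; a direct
  # simplex search over the 2-dof control point escapes it, and the
  # projection/solve alternation then polishes to machine precision
  opt <- stats::optim(p1, objective, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 500L))
  p1 <- opt$par
  best_val <- opt$value
  for (iter in seq_len(60L)) {
    ti <- project(p1)
    p1_new <- solve_p1(ti)
    moved <- max(abs(p1_new - p1))
    val <- objective(p1_new)
    if (val > best_val * (1 + 1e-9) + 1e-300) break # keep the better fit
    best_val <- val
    p1 <- p1_new
    if (moved < 1e-12) break
  }
  arc <- bezier_arc(O, p1, endpoint, side = side)
  arc$rms_px <- sqrt(objective(p1))
  arc
}

#' Measure the vascular arcades angle on a fundus photograph
#'
#' Runs the full pipeline: ROI extraction and enhancement, optic-disc
#' segmentation (centre O, papillary diameter PD), vessel segmentation
#' and arcade tracing, key points B and C on the 3 PD circle, quadratic
#' Bezier fitting of the two arcade arms, crossings D, E with the 2 PD
#' circle and F, G with the 1 PD circle, and the two angles
#' `vaa_1pd_deg = angle FOG` and `vaa_2pd_deg = angle DOE`.
#'
#' Failures of individual stages do not abort the measurement: the angles
#' are left `NA` and the explaining flag (`disc_low_confidence`,
#' `arcade_missing`, `no_2pd_crossing`, `roi_clipped`) is recorded.
#'
#' @param image An image (path, `EBImage::Image`, array) or a
#'   [generate_fundus_scene()] result.
#' @param config A [vaa_config()].
#' @param disc_bbox Optional externally supplied disc box
#'   `c(x0, y0, x1, y1)` (bypasses the detector).
#' @param keep_artifacts Keep intermediate stage outputs (ROI, disc,
#'   vessel map, traces, arcs) in the result for QC.
#' @return An object of class `vaa_measurement` with fields
#'   `vaa_1pd_deg`, `vaa_2pd_deg`, `pd_px`, points `O`, `B`, `C`, `D`,
#'   `E`, `F`, `G`, `qc_flags`, `residuals` and (optionally)
#'   `artifacts`.
#' @examples
#' \donttest{
#' sc <- generate_fundus_scene(scene_params(seed = 3))
#' m <- measure_vaa(sc)
#' c(m$vaa_1pd_deg, sc$truth$true_vaa_1pd_deg)
#' }
#' @export
measure_vaa <- function(image, config = vaa_config(), disc_bbox = NULL,
                        keep_artifacts = TRUE) {
  stopifnot(inherits(config, "vaa_config"))
  if (inherits(image, "fundus_scene")) image <- image$image
  flags <- character(0)
  out <- list(vaa_1pd_deg = NA_real_, vaa_2pd_deg = NA_real_,
              pd_px = NA_real_, O = NULL, B = NULL, C = NULL,
              D = NULL, E = NULL, F = NULL, G = NULL,
              qc_flags = character(0), residuals = NULL, artifacts = NULL)
  fail <- function(flag) {
    flags <<- union(flags, flag)
    NULL
  }

  roi <- tryCatch(
    extract_roi(image, border_threshold = config$preprocess.border_threshold),
    vaangle_error = function(e) fail("roi_clipped")
  )
  if (is.null(roi)) return(.finish_measurement(out, flags, keep_artifacts, NULL))

  roi <- normalize_enhance(
    roi,
    target_mean = config$preprocess.target_mean,
    target_sd = config$preprocess.target_sd,
    median_size = config$preprocess.median_size,
    clip_limit = config$preprocess.clip_limit,
    tile_size = config$preprocess.tile_size,
    denoise = config$preprocess.denoise,
    normalize = config$preprocess.normalize,
    enhance = config$preprocess.enhance
  )
  arts <- list(roi = roi)

  vess <- compute_vesselness(roi)
  arts$vesselness <- vess

  disc <- tryCatch(
    segment_disc(
      roi, bbox = disc_bbox,
      center_mode = config$disc.center_mode,
      vesselness = vess,
      score_floor = config$disc.score_floor,
      vessel_weight = config$disc.vessel_weight,
      n_theta = config$disc.n_theta,
      rho_step = config$disc.rho_step,
      edge_sigma = config$disc.edge_sigma,
      edge_floor = config$disc.edge_floor
    ),
    vaangle_error = function(e) fail("disc_low_confidence")
  )
  if (is.null(disc)) return(.finish_measurement(out, flags, keep_artifacts, arts))
  if (disc$confidence < 0.3) flags <- union(flags, "disc_low_confidence")
  out$O <- disc$center_px
  out$pd_px <- disc$pd_px
  arts$disc <- disc

  min_size <- config$vessel.min_component_px
  if (is.na(min_size)) min_size <- NULL
  vmap <- binarize_and_skeletonize(
    vess,
    high = config$vessel.high_threshold,
    low = config$vessel.low_threshold,
    min_size = min_size
  )
  arts$vessel_map <- vmap

  arcades <- tryCatch(
    trace_arcades(vmap, disc,
                  ring_radius_pd = config$vessel.ring_radius_pd,
                  target_radius_pd = config$vaa.radius_3pd),
    vaangle_error = function(e) fail("arcade_missing")
  )
  if (is.null(arcades)) return(.finish_measurement(out, flags, keep_artifacts, arts))
  arts$arcades <- arcades

  O <- disc$center_px
  pd <- disc$pd_px
  kp <- tryCatch(
    list(
      B = locate_point_B(arcades$inferior, disc,
                         radius_pd = config$vaa.radius_3pd),
      C = locate_point_C(arcades$superior, disc,
                         radius_pd = config$vaa.radius_3pd,
                         rule = config$vaa.point_c_rule)
    ),
    vaangle_error = function(e) fail("arcade_missing")
  )
  if (is.null(kp)) return(.finish_measurement(out, flags, keep_artifacts, arts))
  out$B <- kp$B
  out$C <- kp$C

  # fit each arm on its side's widest traced vessel
  arc_inf <- fit_bezier_arc(arcades$inferior[[1]], O, kp$B)
  arc_inf$side <- "inferior"
  arc_sup <- fit_bezier_arc(arcades$superior[[1]], O, kp$C)
  arc_sup$side <- "superior"
  arts$arcs <- list(inferior = arc_inf, superior = arc_sup)
  out$residuals <- c(inferior_rms_px = arc_inf$rms_px,
                     superior_rms_px = arc_sup$rms_px)

  cross <- tryCatch(
    list(
      D = circle_arc_intersection(arc_inf, O, 2 * pd, n_scan = config$vaa.n_scan)$point,
      E = circle_arc_intersection(arc_sup, O, 2 * pd, n_scan = config$vaa.n_scan)$point,
      F = circle_arc_intersection(arc_inf, O, pd, n_scan = config$vaa.n_scan)$point,
      G = circle_arc_intersection(arc_sup, O, pd, n_scan = config$vaa.n_scan)$point
    ),
    vaangle_error = function(e) fail("no_2pd_crossing")
  )
  if (is.null(cross)) return(.finish_measurement(out, flags, keep_artifacts, arts))
  out[c("D", "E", "F", "G")] <- cross
  out$vaa_1pd_deg <- angle_at_O(O, cross$F, cross$G)
  out$vaa_2pd_deg <- angle_at_O(O, cross$D, cross$E)

  .finish_measurement(out, flags, keep_artifacts, arts)
}

.finish_measurement <- function(out, flags, keep_artifacts, arts) {
  out$qc_flags <- flags
  if (keep_artifacts) out$artifacts <- arts
  class(out) <- "vaa_measurement"
  out
}

#' @export
print.vaa_measurement <- function(x, ...) {
  cat(sprintf("<vaa_measurement> VAA(1PD)=%s deg VAA(2PD)=%s deg PD=%s px%s\n",
              .fmt2(x$vaa_1pd_deg), .fmt2(x$vaa_2pd_deg), .fmt2(x$pd_px),
              if (length(x$qc_flags)) paste0(" flags: ", paste(x$qc_flags, collapse = ",")) else ""))
  invisible(x)
}

.fmt2 <- function(v) if (is.null(v) || is.na(v)) "NA" else sprintf("%.2f", v)

#' @export
#' @method as_tibble vaa_measurement
as_tibble.vaa_measurement <- function(x, ...) {
  tibble::tibble(
    vaa_1pd_deg = x$vaa_1pd_deg,
    vaa_2pd_deg = x$vaa_2pd_deg,
    pd_px = x$pd_px,
    qc_flags = paste(x$qc_flags, collapse = ";")
  )
}

#' Turn a measurement into a tidy one-row tibble
#'
#' @param x A [measure_vaa()] result.
#' @param ... Unused.
#' @return A one-row tibble with the angles, the papillary diameter, the
#'   key/crossing point coordinates and the QC flags.
#' @export
#' @method tidy vaa_measurement
tidy.vaa_measurement <- function(x, ...) {
  pt <- function(p, nm) {
    if (is.null(p)) {
      stats::setNames(list(NA_real_, NA_real_), paste0(nm, c("_x", "_y")))
    } else {
      stats::setNames(list(p[1], p[2]), paste0(nm, c("_x", "_y")))
    }
  }
  tibble::as_tibble(c(
    list(vaa_1pd_deg = x$vaa_1pd_deg, vaa_2pd_deg = x$vaa_2pd_deg,
         pd_px = x$pd_px),
    pt(x$O, "o"), pt(x$B, "b"), pt(x$C, "c"), pt(x$D, "d"),
    pt(x$E, "e"), pt(x$F, "f"), pt(x$G, "g"),
    list(qc_flags = paste(x$qc_flags, collapse = ";"))
  ))
}

#' Serialize a measurement to JSON
#'
#' @param x A [measure_vaa()] result.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_measurement_json <- function(x, path) {
  stopifnot(inherits(x, "vaa_measurement"))
  obj <- list(
    vaa_1pd_deg = round(x$vaa_1pd_deg, 2),
    vaa_2pd_deg = round(x$vaa_2pd_deg, 2),
    pd_px = x$pd_px,
    O = x$O, B = x$B, C = x$C, D = x$D, E = x$E, F = x$F, G = x$G,
    qc_flags = as.list(x$qc_flags),
    residuals = as.list(x$residuals)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
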