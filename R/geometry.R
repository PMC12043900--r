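# Plane geometry for the arcade-angle method: quadratic Bezier curves,
# circle crossings, angles at the disc centre, minimum enclosing circle.
# Points are numeric length-2 vectors (x, y), pixel units, origin top-left,
# y increasing downwards.

#' Evaluate a quadratic Bezier curve
#'
#' @param p0,p1,p2 Numeric length-2 points: start, control, end.
#' @param t Numeric vector of curve parameters in `[0, 1]`.
#' @return A `length(t)` x 2 matrix of points on the curve.
#' @examples
#' bezier_point(c(0, 0), c(1, 1), c(2, 0), c(0, 0.5, 1))
#' @export
bezier_point <- function(p0, p1, p2, t) {
  stopifnot(length(p0) == 2, length(p1) == 2, length(p2) == 2)
  a <- (1 - t)^2
  b <- 2 * t * (1 - t)
  d <- t^2
  cbind(a * p0[1] + b * p1[1] + d * p2[1],
        a * p0[2] + b * p1[2] + d * p2[2])
}

#' Unsigned angle at a vertex
#'
#' Angle between the rays `O -> P` and `O -> Q`, computed with the
#' two-argument arctangent of cross and dot products so that values near
#' 0 and 180 degrees remain accurate.
#'
#' @param O,P,Q Numeric length-2 points; `P` and `Q` must differ from `O`.
#' @return The angle in degrees, in `[0, 180]`.
#' @examples
#' angle_at_O(c(0, 0), c(1, 0), c(0, 1)) # 90
#' @export
angle_at_O <- function(O, P, Q) {
  u <- P - O
  v <- Q - O
  if (all(u == 0) || all(v == 0)) {
    stop_vaangle("angle_at_O: P and Q must differ from O", "degenerate_angle")
  }
  cross <- u[1] * v[2] - u[2] * v[1]
  dot <- sum(u * v)
  atan2(abs(cross), dot) * 180 / pi
}

#' Outermost crossing of a quadratic Bezier arc with a circle
#'
#' Finds t in `[0, 1]` with `|P(t) - O| = radius` by a sign-change scan
#' followed by bisection, and returns the crossing with the largest t
#' (the outbound crossing) when the arc crosses more than once.
#'
#' @param arc A [bezier_arc()] or any list with fields `p0`, `p1`, `p2`.
#' @param O Circle centre (length-2 numeric).
#' @param radius Circle radius (> 0), pixels.
#' @param n_scan Number of scan samples for bracketing (default 256).
#' @return A list with `point` (length-2) and `t`.
#' @export
circle_arc_intersection <- function(arc, O, radius, n_scan = 256L) {
  stopifnot(radius > 0)
  f <- function(t) {
    p <- bezier_point(arc$p0, arc$p1, arc$p2, t)
    sqrt((p[, 1] - O[1])^2 + (p[, 2] - O[2])^2) - radius
  }
  ts <- seq(0, 1, length.out = n_scan + 1L)
  fv <- f(ts)
  sgn <- sign(fv)
  sgn[sgn == 0] <- 1e-300 # treat exact zeros as crossings of either side
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0 | fv[-1] == 0)
  if (length(idx) == 0) {
    if (any(fv == 0)) {
      t0 <- ts[max(which(fv == 0))]
      return(list(point = drop(bezier_point(arc$p0, arc$p1, arc$p2, t0)), t = t0))
    }
    stop_vaangle(
      sprintf("arc does not cross the circle of radius %.6g", radius),
      "no_intersection"
    )
  }
  i <- max(idx) # outermost crossing
  lo <- ts[i]
  hi <- ts[i + 1L]
  flo <- fv[i]
  for (iter in seq_len(200L)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < 1e-9 * radius || (hi - lo) < 1e-14) break
    if (sign(fm) == sign(flo)) {
      lo <- mid
      flo <- fm
    } else {
      hi <- mid
    }
  }
  t_star <- (lo + hi) / 2
  list(point = drop(bezier_point(arc$p0, arc$p1, arc$p2, t_star)), t = t_star)
}

#' Construct a quadratic Bezier arc
#'
#' @param p0,p1,p2 Start, control, end points (length-2 numeric).
#' @param side Optional `"superior"` or `"inferior"` tag.
#' @return An object of class `bezier_arc`.
#' @export
bezier_arc <- function(p0, p1, p2, side = NA_character_) {
  structure(list(p0 = as.numeric(p0), p1 = as.numeric(p1),
                 p2 = as.numeric(p2), side = side),
            class = "bezier_arc")
}

#' @export
print.bezier_arc <- function(x, ...) {
  cat(sprintf("<bezier_arc %s> P0=(%.1f,%.1f) P1=(%.1f,%.1f) P2=(%.1f,%.1f)\n",
              x$side, x$p0[1], x$p0[2], x$p1[1], x$p1[2], x$p2[1], x$p2[2]))
  invisible(x)
}

#' Analytic vascular-arcades angle for known arcs
#'
#' The exact angle at `O` subtended by the outermost crossings of two
#' quadratic Bezier arcades with the circle of the given radius. This is
#' the ground-truth counterpart of the image-based measurement: both arcs
#' must start at `O` and cross the circle.
#'
#' @param arcs A list of two [bezier_arc()] objects, each with `p0 = O`.
#' @param O The disc centre (length-2 numeric).
#' @param radius Measurement-circle radius in pixels (1 or 2 papillary
#'   diameters in the standard protocol).
#' @return Angle in degrees.
#' @export
analytic_vaa <- function(arcs, O, radius) {
  stopifnot(length(arcs) == 2)
  for (a in arcs) {
    if (max(abs(a$p0 - O)) > 1e-6) {
      stop_vaangle("each arc must start at O", "invalid_params")
    }
  }
  q1 <- circle_arc_intersection(arcs[[1]], O, radius)$point
  q2 <- circle_arc_intersection(arcs[[2]], O, radius)$point
  angle_at_O(O, q1, q2)
}

#' First crossing of a polyline with a circle
#'
#' Walks the polyline in order and returns the first point where it
#' crosses the circle `|p - O| = radius` (inside to outside), solving the
#' segment-circle quadratic on the crossing segment.
#'
#' @param points An n x 2 matrix of polyline vertices.
#' @param O Circle centre.
#' @param radius Circle radius (> 0).
#' @return The crossing point (length-2 numeric).
#' @export
polyline_circle_crossing <- function(points, O, radius) {
  stopifnot(is.matrix(points), ncol(points) == 2, nrow(points) >= 2, radius > 0)
  r <- sqrt((points[, 1] - O[1])^2 + (points[, 2] - O[2])^2)
  n <- nrow(points)
  cross_seg <- which(r[-n] < radius & r[-1] >= radius)
  if (length(cross_seg) == 0) {
    stop_vaangle("polyline does not cross the circle", "no_intersection")
  }
  i <- cross_seg[1]
  a <- points[i, ] - O
  d <- points[i + 1L, ] - points[i, ]
  # |a + s d| = radius, s in [0, 1]
  A <- sum(d^2)
  B <- 2 * sum(a * d)
  C <- sum(a^2) - radius^2
  disc <- B^2 - 4 * A * C
  disc <- max(disc, 0)
  s <- (-B + sqrt(disc)) / (2 * A)
  s <- min(max(s, 0), 1)
  points[i, ] + s * d
}

#' Minimum enclosing circle
#'
#' Smallest circle containing all the input points (Welzl's randomized
#' incremental algorithm). Used to turn the segmented disc boundary into
#' the disc centre `O` and the papillary diameter.
#'
#' @param points An n x 2 matrix (n >= 2, at least two distinct points).
#' @return A list with `center` (length-2) and `radius`.
#' @examples
#' min_enclosing_circle(cbind(c(0, 1, 0), c(0, 0, 1)))
#' @export
min_enclosing_circle <- function(points) {
  stopifnot(is.matrix(points), ncol(points) == 2)
  points <- points[stats::complete.cases(points), , drop = FALSE]
  pts <- unique(points)
  if (nrow(pts) < 2) {
    stop_vaangle("need at least 2 distinct points", "invalid_params")
  }
  n <- nrow(pts)
  # deterministic shuffle: expected linear time regardless of input order
  rs <- .preserve_rng()
  on.exit(.restore_rng(rs), add = TRUE)
  set.seed(421731L)
  pts <- pts[sample.int(n), , drop = FALSE]

  inside <- function(circ, p) {
    sum((p - circ$center)^2) <= circ$radius^2 * (1 + 1e-12) + 1e-12
  }
  circ2 <- function(p, q) {
    list(center = (p + q) / 2, radius = sqrt(sum((p - q)^2)) / 2)
  }
  circ3 <- function(p, q, r) {
    ax <- p[1]; ay <- p[2]; bx <- q[1]; by <- q[2]; cx <- r[1]; cy <- r[2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) {
      # collinear: largest pairwise circle
      cands <- list(circ2(p, q), circ2(p, r), circ2(q, r))
      return(cands[[which.max(vapply(cands, `[[`, numeric(1), "radius"))]])
    }
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    ctr <- c(ux, uy)
    list(center = ctr, radius = sqrt(sum((p - ctr)^2)))
  }

  circ <- circ2(pts[1, ], pts[2, ])
  if (n > 2) {
    for (i in 3:n) {
      pi_ <- pts[i, ]
      if (inside(circ, pi_)) next
      circ <- circ2(pts[1, ], pi_)
      for (j in 2:(i - 1)) {
        pj <- pts[j, ]
        if (inside(circ, pj)) next
        circ <- circ2(pi_, pj)
        if (j >= 2) {
          for (k in 1:(j - 1)) {
            pk <- pts[k, ]
            if (inside(circ, pk)) next
            circ <- circ3(pi_, pj, pk)
          }
        }
      }
    }
  }
  circ
}

# ---- internal helpers -------------------------------------------------------

stop_vaangle <- function(message, subclass, ...) {
  stop(structure(
    class = c(paste0("vaangle_", subclass), "vaangle_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

.preserve_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_rng <- function(rs) {
  if (!is.null(rs)) {
    assign(".Random.seed", rs, envir = globalenv())
  } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    rm(".Random.seed", envir = globalenv())
  }
  invisible(NULL)
}
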