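# Independent oracles kept deliberately naive: a dense-sampling circle
# crossing finder and an exhaustive minimum-enclosing-circle search.

# outermost circle crossing by dense scan (1e5 samples) + bisection on
# the bracketing interval; independent of circle_arc_intersection
oracle_circle_crossing <- function(arc, O, radius, n = 1e5L) {
  tt <- seq(0, 1, length.out = n)
  p <- bezier_point(arc$p0, arc$p1, arc$p2, tt)
  f <- sqrt((p[, 1] - O[1])^2 + (p[, 2] - O[2])^2) - radius
  sgn <- sign(f)
  idx <- which(sgn[-1] * sgn[-n] < 0 | f[-1] == 0)
  if (length(idx) == 0) return(NULL)
  i <- max(idx)
  lo <- tt[i]
  hi <- tt[i + 1]
  fl <- f[i]
  g <- function(t) {
    q <- drop(bezier_point(arc$p0, arc$p1, arc$p2, t))
    sqrt(sum((q - O)^2)) - radius
  }
  for (k in 1:100) {
    mid <- (lo + hi) / 2
    fm <- g(mid)
    if (sign(fm) == sign(fl)) {
      lo <- mid
      fl <- fm
    } else {
      hi <- mid
    }
  }
  drop(bezier_point(arc$p0, arc$p1, arc$p2, (lo + hi) / 2))
}

# exhaustive minimum enclosing circle: every circle through 2 or 3
# support points, keep those enclosing all points, take the smallest
oracle_mec <- function(pts) {
  n <- nrow(pts)
  contains_all <- function(ctr, r) {
    all(sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2) <= r * (1 + 1e-9))
  }
  best <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ctr <- (pts[i, ] + pts[j, ]) / 2
    r <- sqrt(sum((pts[i, ] - pts[j, ])^2)) / 2
    if (contains_all(ctr, r) && (is.null(best) || r < best$radius)) {
      best <- list(center = ctr, radius = r)
    }
  }
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- pts[i, ]; b <- pts[j, ]; c_ <- pts[k, ]
    d <- 2 * (a[1] * (b[2] - c_[2]) + b[1] * (c_[2] - a[2]) + c_[1] * (a[2] - b[2]))
    if (abs(d) < 1e-12) next
    ux <- ((a[1]^2 + a[2]^2) * (b[2] - c_[2]) + (b[1]^2 + b[2]^2) * (c_[2] - a[2]) +
             (c_[1]^2 + c_[2]^2) * (a[2] - b[2])) / d
    uy <- ((a[1]^2 + a[2]^2) * (c_[1] - b[1]) + (b[1]^2 + b[2]^2) * (a[1] - c_[1]) +
             (c_[1]^2 + c_[2]^2) * (b[1] - a[1])) / d
    ctr <- c(ux, uy)
    r <- sqrt(sum((a - ctr)^2))
    if (contains_all(ctr, r) && (is.null(best) || r < best$radius)) {
      best <- list(center = ctr, radius = r)
    }
  }
  best
}

# a random quadratic arc starting at O and leaving the given radius
random_outgoing_arc <- function(O, reach) {
  th <- stats::runif(1, 0, 2 * pi)
  p2 <- O + reach * stats::runif(1, 1.1, 2) * c(cos(th), sin(th))
  p1 <- O + reach * stats::runif(1, 0.3, 1.2) *
    c(cos(th + stats::runif(1, -0.8, 0.8)), sin(th + stats::runif(1, -0.8, 0.8)))
  bezier_arc(O, p1, p2)
}
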