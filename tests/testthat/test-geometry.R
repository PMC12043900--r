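test_that("angle_at_O matches hand values and the arccos formula", {
  expect_equal(angle_at_O(c(0, 0), c(1, 0), c(0, 1)), 90)
  expect_equal(angle_at_O(c(0, 0), c(1, 0), c(-1, 0)), 180)
  expect_error(angle_at_O(c(0, 0), c(0, 0), c(1, 1)), class = "vaangle_error")

  set.seed(11)
  for (i in 1:1000) {
    O <- rnorm(2)
    P <- O + rnorm(2)
    Q <- O + rnorm(2)
    a <- angle_at_O(O, P, Q)
    u <- (P - O) / sqrt(sum((P - O)^2))
    v <- (Q - O) / sqrt(sum((Q - O)^2))
    ref <- acos(min(max(sum(u * v), -1), 1)) * 180 / pi
    tol <- if (ref < 1 || ref > 179) 1e-5 else 1e-9
    expect_lt(abs(a - ref), tol)
  }
})

test_that("circle_arc_intersection handles linear, inside and exact cases", {
  straight <- bezier_arc(c(0, 0), c(100, 0), c(200, 0))
  hit <- circle_arc_intersection(straight, c(0, 0), 75)
  expect_equal(hit$point, c(75, 0), tolerance = 1e-6)

  inside <- bezier_arc(c(0, 0), c(5, 5), c(10, 0))
  expect_error(circle_arc_intersection(inside, c(0, 0), 1000),
               class = "vaangle_no_intersection")
})

test_that("circle_arc_intersection matches the dense-scan oracle", {
  set.seed(21)
  n_bad <- 0
  for (i in 1:50) {
    O <- runif(2, -50, 50)
    radius <- runif(1, 20, 120)
    arc <- random_outgoing_arc(O, radius)
    ref <- oracle_circle_crossing(arc, O, radius)
    if (is.null(ref)) next
    got <- circle_arc_intersection(arc, O, radius)$point
    if (sqrt(sum((got - ref)^2)) > 1e-3 * radius) n_bad <- n_bad + 1
  }
  expect_equal(n_bad, 0)
})

test_that("min_enclosing_circle reproduces closed-form cases", {
  eq <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  mec <- min_enclosing_circle(eq)
  expect_equal(mec$radius, 1 / sqrt(3), tolerance = 1e-9)

  two <- rbind(c(-3, 4), c(5, -2))
  mec2 <- min_enclosing_circle(two)
  expect_equal(mec2$center, c(1, 1), tolerance = 1e-12)
  expect_equal(mec2$radius, sqrt(sum((two[1, ] - two[2, ])^2)) / 2,
               tolerance = 1e-12)

  expect_error(min_enclosing_circle(rbind(c(1, 1), c(1, 1))),
               class = "vaangle_invalid_params")
})

test_that("min_enclosing_circle matches the exhaustive oracle and is monotone", {
  set.seed(31)
  for (i in 1:25) {
    pts <- matrix(runif(20, -10, 10), ncol = 2)
    got <- min_enclosing_circle(pts)
    ref <- oracle_mec(pts)
    expect_equal(got$radius, ref$radius, tolerance = 1e-9)
    # every point inside
    d <- sqrt((pts[, 1] - got$center[1])^2 + (pts[, 2] - got$center[2])^2)
    expect_true(all(d <= got$radius * (1 + 1e-9)))
    # adding points never shrinks the circle
    extra <- rbind(pts, matrix(runif(10, -10, 10), ncol = 2))
    expect_gte(min_enclosing_circle(extra)$radius, got$radius - 1e-9)
  }
})

test_that("polyline_circle_crossing solves the crossing segment exactly", {
  # straight polyline along +x crossing radius 5 between the 2nd and 3rd vertex
  pl <- cbind(c(0, 3, 7, 10), c(0, 0, 0, 0))
  expect_equal(polyline_circle_crossing(pl, c(0, 0), 5), c(5, 0))
  expect_error(polyline_circle_crossing(pl, c(0, 0), 50),
               class = "vaangle_no_intersection")
})

test_that("analytic_vaa is radius-independent for straight rays", {
  O <- c(10, 20)
  mk_ray <- function(th) {
    d <- c(cos(th), sin(th))
    bezier_arc(O, O + 100 * d, O + 200 * d)
  }
  arcs <- list(mk_ray(0.3), mk_ray(0.3 + 130 * pi / 180))
  a1 <- analytic_vaa(arcs, O, 40)
  a2 <- analytic_vaa(arcs, O, 150)
  expect_equal(a1, 130, tolerance = 1e-9)
  expect_lt(abs(a1 - a2), 1e-9)
})

test_that("analytic_vaa of mirror-image arcs is bisected by the mirror axis", {
  O <- c(0, 0)
  up <- bezier_arc(O, c(-60, -90), c(-150, -140))
  dn <- bezier_arc(O, c(-60, 90), c(-150, 140))
  for (r in c(50, 110)) {
    p_up <- circle_arc_intersection(up, O, r)$point
    p_dn <- circle_arc_intersection(dn, O, r)$point
    expect_equal(p_up[1], p_dn[1], tolerance = 1e-9)
    expect_equal(p_up[2], -p_dn[2], tolerance = 1e-9)
    full <- analytic_vaa(list(up, dn), O, r)
    half <- angle_at_O(O, p_up, c(-1, 0))
    expect_equal(full, 2 * half, tolerance = 1e-9)
  }
})
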