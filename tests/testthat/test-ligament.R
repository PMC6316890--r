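# Ligament constitutive law, wrapping, sectioning

test_that("engineering strain is (l - l0)/l0", {
  expect_equal(engineering_strain(10, 10), 0)
  expect_equal(engineering_strain(15, 10), 0.5)
  expect_equal(engineering_strain(9, 10), -0.1)
  expect_error(engineering_strain(10, 0), "positive")
  expect_error(engineering_strain(10, -1), "positive")
})

test_that("elastic force has toe, linear and slack branches", {
  expect_equal(bundle_elastic_force(-0.05, 100, 0.03), 0)
  # branch point 2*eps_l: both expressions give k*eps_l = 3.0
  expect_equal(bundle_elastic_force(0.06, 100, 0.03), 3.0)
  expect_equal(0.25 * 100 * 0.06^2 / 0.03, 100 * (0.06 - 0.03))
  expect_equal(bundle_elastic_force(0.10, 100, 0.03), 7.0)
  # toe region example: quarter-quadratic
  expect_equal(bundle_elastic_force(0.03, 100, 0.03),
               0.25 * 100 * 0.03^2 / 0.03)
})

test_that("force-strain law is C1 at the branch point for random parameters", {
  set.seed(3)
  for (i in 1:50) {
    k <- runif(1, 10, 500)
    el <- runif(1, 0.005, 0.08)
    br <- 2 * el
    expect_equal(bundle_elastic_force(br - 1e-9, k, el),
                 bundle_elastic_force(br + 1e-9, k, el), tolerance = 1e-5)
    h <- 1e-7
    slope_lo <- (bundle_elastic_force(br - h, k, el) -
                   bundle_elastic_force(br - 2 * h, k, el)) / h
    slope_hi <- (bundle_elastic_force(br + 2 * h, k, el) -
                   bundle_elastic_force(br + h, k, el)) / h
    expect_equal(slope_lo, k, tolerance = 1e-4)
    expect_equal(slope_hi, k, tolerance = 1e-4)
  }
})

test_that("elastic force is non-decreasing in strain and zero at l0", {
  set.seed(4)
  eps <- sort(runif(300, -0.3, 0.8))
  f <- bundle_elastic_force(eps, 217, 0.03)
  expect_true(all(diff(f) >= -1e-12))
  expect_equal(bundle_elastic_force(0, 217, 0.03), 0)
})

test_that("total bundle force adds the damper and clamps at zero", {
  b <- ligament_bundle("x", "MCL_AB", "humerus", c(0, 0, 0),
                       "ulna", c(10, 0, 0), k = 100, l0 = 10)
  # slack, no rate
  expect_equal(bundle_total_force(list(l = 9, l_dot = 0), b), 0)
  # elastic 3.0 N plus damper 0.5 * 2
  expect_equal(bundle_total_force(list(l = 10.6, l_dot = 2), b), 4.0)
  # damper cannot make the ligament push
  expect_equal(bundle_total_force(list(l = 9.9, l_dot = -10), b), 0)
  b$active <- FALSE
  expect_equal(bundle_total_force(list(l = 20, l_dot = 0), b), 0)
})

test_that("straight routing returns the chord", {
  rt <- wrap_route(c(0, 0, 0), c(10, 0, 0))
  expect_equal(rt$length, 10)
  expect_false(rt$wrapped)
  expect_equal(rt$dir_origin, c(1, 0, 0))
  expect_equal(rt$dir_insertion, c(-1, 0, 0))
  # primitive far from the segment leaves the straight path
  far <- wrap_sphere("radius", c(0, 50, 0), 3)
  far$center <- c(0, 50, 0)
  rt2 <- wrap_route(c(0, 0, 0), c(10, 0, 0), list(far))
  expect_equal(rt2$length, 10)
  expect_false(rt2$wrapped)
})

test_that("sphere wrap matches the closed form and a graph-search oracle", {
  r <- 3
  A <- c(-2 * r, 0, 0)
  B <- c(2 * r, 0, 0)
  sph <- wrap_sphere("radius", c(0, 0, 0), r)
  rt <- wrap_route(A, B, list(sph))
  expect_true(rt$wrapped)
  closed <- 2 * r * sqrt(3) + r * (pi - 2 * acos(1 / 2))
  expect_equal(rt$length, closed, tolerance = 1e-9)
  skip_if_not_installed("igraph")
  # independent oracle: dense shortest-path graph around the obstacle
  # circle in the wrap plane (tangent-visibility edges + arc edges)
  npt <- 1440
  th <- seq(0, 2 * pi, length.out = npt + 1)[-(npt + 1)]
  pts <- rbind(A[1:2], B[1:2], cbind(r * cos(th), r * sin(th)))
  seg_clear <- function(p, q) {
    d <- q - p
    t0 <- -sum(p * d) / sum(d * d)
    t0 <- min(max(t0, 0), 1)
    sqrt(sum((p + t0 * d)^2)) >= r - 1e-9
  }
  edges <- list(); w <- c()
  for (i in 1:2) for (j in 3:(npt + 2)) {
    if (seg_clear(pts[i, ], pts[j, ])) {
      edges[[length(edges) + 1]] <- c(i, j)
      w <- c(w, sqrt(sum((pts[i, ] - pts[j, ])^2)))
    }
  }
  for (j in 3:(npt + 2)) {
    jn <- if (j == npt + 2) 3 else j + 1
    edges[[length(edges) + 1]] <- c(j, jn)
    w <- c(w, 2 * r * sin(pi / npt))
  }
  if (seg_clear(pts[1, ], pts[2, ])) {
    edges[[length(edges) + 1]] <- c(1, 2)
    w <- c(w, sqrt(sum((pts[1, ] - pts[2, ])^2)))
  }
  g <- igraph::make_graph(t(do.call(rbind, edges)), directed = FALSE,
                          n = npt + 2)
  dg <- igraph::distances(g, v = 1, to = 2, weights = w)[1, 1]
  expect_equal(rt$length, dg, tolerance = 0.005 * rt$length)
})

test_that("cylinder wrap develops correctly and handles axial offset", {
  r <- 3
  cyl <- wrap_cylinder("radius", c(0, 0, 0), c(0, 0, 1), r)
  # in-plane case must agree with the circle closed form
  A <- c(-2 * r, 0, 0); B <- c(2 * r, 0, 0)
  rt <- wrap_route(A, B, list(cyl))
  closed <- 2 * r * sqrt(3) + r * (pi - 2 * acos(1 / 2))
  expect_equal(rt$length, closed, tolerance = 1e-9)
  # axial offset: developed length via Pythagoras on the unrolled surface
  B2 <- c(2 * r, 0, 7)
  rt2 <- wrap_route(A, B2, list(cyl))
  expect_equal(rt2$length, sqrt(closed^2 + 49), tolerance = 1e-9)
  expect_gt(rt2$length, sqrt(sum((B2 - A)^2)))  # longer than the chord
})

test_that("endpoints inside a primitive raise (or clamp on request)", {
  sph <- wrap_sphere("radius", c(0, 0, 0), 5)
  expect_error(wrap_route(c(1, 0, 0), c(10, 0, 0), list(sph)),
               "origin.*primitive 1")
  expect_error(wrap_route(c(10, 0, 0), c(1, 0, 0), list(sph)),
               "insertion.*primitive 1")
  expect_silent(wrap_route(c(1, 0, 0), c(10, 0, 0), list(sph), clamp = TRUE))
})

test_that("path length is continuous under small endpoint motion", {
  r <- 4
  sph <- wrap_sphere("radius", c(0, 0, 0), r)
  base <- wrap_route(c(-10, 1, 0), c(10, 1, 0), list(sph))$length
  for (h in c(1e-4, 1e-3)) {
    moved <- wrap_route(c(-10, 1 + h, 0), c(10, 1, 0), list(sph))$length
    expect_lt(abs(moved - base), 10 * h)
  }
  # across the wrap-activation boundary the length is continuous too
  yact <- r  # segment tangent to the sphere at y = r
  lo <- wrap_route(c(-10, yact - 1e-6, 0), c(10, yact - 1e-6, 0), list(sph))
  hi <- wrap_route(c(-10, yact + 1e-6, 0), c(10, yact + 1e-6, 0), list(sph))
  expect_lt(abs(lo$length - hi$length), 1e-3)
  expect_true(lo$wrapped)
  expect_false(hi$wrapped)
})

test_that("scenario sectioning deactivates exactly the named complexes", {
  geo <- small_geo()
  atlas <- geo$atlas
  expect_equal(length(atlas$bundles), 14)
  expect_equal(n_active_bundles(section_bundles(atlas, "intact")), 14)
  ab <- section_bundles(atlas, "MCL_AB_deficient")
  expect_equal(n_active_bundles(ab), 11)
  inact <- vapply(ab$bundles, function(b) !b$active, TRUE)
  expect_true(all(vapply(ab$bundles[inact], function(b)
    b$complex == "MCL_AB", TRUE)))
  pb <- section_bundles(atlas, "MCL_PB_deficient")
  expect_equal(n_active_bundles(pb), 11)
  both <- section_bundles(atlas, "both_MCL_deficient")
  expect_equal(n_active_bundles(both), 8)
  # idempotent and reversible via intact
  expect_equal(n_active_bundles(section_bundles(both, "both_MCL_deficient")), 8)
  expect_equal(n_active_bundles(section_bundles(both, "intact")), 14)
  expect_error(section_bundles(atlas, "no_such"), "valid")
})
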