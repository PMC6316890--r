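# Contact law: Hertzian force with smoothstep damping, elastic foundation

test_that("damping coefficient follows the smoothstep ramp", {
  p <- contact_parameters(kc = 126, Bmax = 2, dmax = 0.1)
  expect_equal(damping_coefficient(-0.01, p), 0)
  expect_equal(damping_coefficient(0, p), 0)
  expect_equal(damping_coefficient(0.1, p), 2)
  expect_equal(damping_coefficient(0.5, p), 2)   # saturated beyond dmax
  # s = 0.5: Bmax * s^2 (3 - 2 s) = 2 * 0.25 * 2 = 1.0
  expect_equal(damping_coefficient(0.05, p), 1.0)
})

test_that("damping ramp is C1 at both boundaries", {
  p <- contact_parameters(kc = 100, Bmax = 2, dmax = 0.1)
  h <- 1e-7
  for (d0 in c(0, 0.1)) {
    below <- (damping_coefficient(d0 - h, p) - damping_coefficient(d0 - 2 * h, p)) / h
    above <- (damping_coefficient(d0 + 2 * h, p) - damping_coefficient(d0 + h, p)) / h
    expect_equal(damping_coefficient(d0 + h, p), damping_coefficient(d0 - h, p),
                 tolerance = 1e-5)
    expect_lt(abs(below - above), 1e-3)
  }
})

test_that("contact normal force matches hand-evaluated values", {
  p_uh <- contact_parameters(kc = 126, n = 1, Bmax = 2, dmax = 0.1)
  p_rh <- contact_parameters(kc = 105, n = 1, Bmax = 2, dmax = 0.1)
  expect_equal(contact_normal_force(0, 123, p_uh), 0)
  expect_equal(contact_normal_force(-0.5, -10, p_uh), 0)
  expect_equal(contact_normal_force(0.05, 0, p_uh), 6.3)
  # saturated damping: 105 * 0.2 + 2 * 1 = 23.0
  expect_equal(contact_normal_force(0.2, 1, p_rh), 23.0)
})

test_that("contact force is continuous in penetration and never adhesive", {
  p <- contact_parameters(kc = 126)
  for (ddot in c(-5, 0, 3)) {
    f <- function(d) contact_normal_force(d, ddot, p)
    for (d0 in c(0, p$dmax))
      expect_lt(abs(f(d0 + 1e-8) - f(d0 - 1e-8)), 1e-4)
  }
  set.seed(7)
  d <- runif(200, -0.1, 0.3)
  dd <- runif(200, -50, 50)
  f <- contact_normal_force(d, dd, p)
  expect_true(all(f >= 0))
  # passivity: for non-negative approach rate the force is at least elastic
  pos <- dd >= 0 & d > 0
  expect_true(all(f[pos] >= p$kc * d[pos] - 1e-12))
})

test_that("elastic foundation stiffness evaluates the layer formula", {
  # derived oracle: direct evaluation of (1-nu) E / ((1+nu)(1-2nu) h) * A
  E <- 0.7; nu <- 0.495; h <- 4; A <- 25
  expected <- (1 - nu) * E / ((1 + nu) * (1 - 2 * nu) * h) * A
  expect_equal(foundation_stiffness(E, nu, h, A), expected)
  expect_equal(expected, 147.8, tolerance = 1e-3)
  # all-unity case and 1/h proportionality
  expect_equal(foundation_stiffness(1, 0, 1, 1), 1)
  expect_equal(foundation_stiffness(E, nu, h / 2, A),
               2 * foundation_stiffness(E, nu, h, A))
  expect_error(foundation_stiffness(E, 0.5, h, A), "incompressible")
  expect_error(foundation_stiffness(-1, nu, h, A), "positive")
})

test_that("element penetration has the right sign and magnitude", {
  # analytic plane as a mesh: z = 0, outward normal +z
  plane <- flat_patch_mesh(40, 40, 10, 10)
  el_in <- contact_element(1, c(17, 21, -0.07), c(0, 0, 1), 25)
  el_out <- contact_element(2, c(17, 21, 0.33), c(0, 0, 1), 25)
  expect_equal(element_penetration(el_in, plane)$delta, 0.07,
               tolerance = 1e-9)
  expect_equal(element_penetration(el_out, plane)$delta, -0.33,
               tolerance = 1e-9)
  # point outside a unit sphere at distance 1 from the surface
  sph <- sphere_mesh(radius = 1, n = 60)
  el_far <- contact_element(3, c(0, 2, 0), c(0, 1, 0), 1)
  expect_equal(element_penetration(el_far, sph)$delta, -1, tolerance = 5e-3)
})

test_that("penetration rate is the projected relative velocity", {
  plane <- flat_patch_mesh(40, 40, 8, 8)
  el <- contact_element(1, c(20, 20, 0.05), c(0, 0, 1), 25)
  # element body approaching the plane at 2 mm/s
  tw <- list(linear = c(0, 0, -2), angular = c(0, 0, 0), ref = c(0, 0, 0))
  out <- element_penetration(el, plane, element_twist = tw)
  expect_equal(out$delta_dot, 2, tolerance = 1e-9)
  # surface body moving up at 1 mm/s adds to the approach
  tws <- list(linear = c(0, 0, 1), angular = c(0, 0, 0), ref = c(0, 0, 0))
  out2 <- element_penetration(el, plane, element_twist = tw,
                              surface_twist = tws)
  expect_equal(out2$delta_dot, 3, tolerance = 1e-9)
})

test_that("pruned mesh distance agrees with an exhaustive oracle", {
  set.seed(11)
  mesh <- cylinder_sector_mesh(r = 12, L = 25, ang = 4, na = 18, nz = 14)
  # brute-force oracle: exact nearest point over every triangle
  brute <- function(p) {
    best <- Inf
    for (i in seq_len(nrow(mesh$faces))) {
      q <- elbowmbs:::closest_point_on_triangle(
        p, mesh$vertices[mesh$faces[i, 1], ],
        mesh$vertices[mesh$faces[i, 2], ],
        mesh$vertices[mesh$faces[i, 3], ])
      best <- min(best, sqrt(sum((p - q)^2)))
    }
    best
  }
  for (k in 1:25) {
    p <- c(runif(1, -20, 20), runif(1, -20, 20), runif(1, -10, 35))
    got <- point_surface_signed_distance(p, mesh)
    expect_equal(abs(got$distance), brute(p), tolerance = 1e-6)
  }
})

test_that("contact map reports pressures, peak and contact area", {
  p <- contact_parameters(kc = 126)
  els <- lapply(1:6, function(i)
    contact_element(i, c(i * 5, 0, 0), c(0, 0, 1), 25,
                    map_uv = c(i * 5, 0)))
  # all separated
  st0 <- data.frame(delta = rep(-0.1, 6), delta_dot = 0, Fc = 0)
  m0 <- contact_map(els, st0)
  expect_equal(m0$contact_area, 0)
  expect_equal(m0$peak_pressure, 0)
  # four elements of a 5 mm grid in contact -> 100 mm^2
  st <- data.frame(delta = c(0.05, 0.04, 0.03, 0.02, -0.01, -0.02),
                   delta_dot = 0, Fc = c(6.3, 5, 4, 3, 0, 0))
  m <- contact_map(els, st)
  expect_equal(m$contact_area, 100)
  expect_equal(m$n_contact, 4)
  expect_equal(m$peak_pressure, 6.3 / 25)
  expect_equal(m$map$pressure[1], 0.252)
})
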