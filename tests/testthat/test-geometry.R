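# Synthetic elbow generator and cartilage discretization

test_that("configuration validation names the offending field", {
  expect_error(geometry_config(trochlea_radius = -1), "trochlea_radius")
  expect_error(geometry_config(element_edge = 0), "element_edge")
  expect_error(geometry_config(ulna_length = -5), "ulna_length")
  expect_error(geometry_config(sigmoid_notch_wrap_angle = 80),
               "sigmoid_notch_wrap_angle")
  expect_error(geometry_config(sigmoid_notch_wrap_angle = 220),
               "sigmoid_notch_wrap_angle")
})

test_that("the atlas carries the standard 14-bundle inventory", {
  geo <- small_geo()
  bundles <- geo$atlas$bundles
  expect_equal(length(bundles), 14)
  cx <- table(vapply(bundles, function(b) b$complex, ""))
  expect_equal(as.vector(cx[c("MCL_AB", "MCL_PB", "LUCL", "RCL", "annular")]),
               c(3L, 3L, 3L, 3L, 2L))
  # all bundles have positive zero-load lengths set from the reference pose
  expect_true(all(vapply(bundles, function(b) b$l0 > 0, TRUE)))
  # MCL complex spans the medial side, LUCL/RCL the lateral side
  me <- geo$landmarks$humerus$medial_epicondyle
  le <- geo$landmarks$humerus$lateral_epicondyle
  for (b in bundles) {
    if (b$complex %in% c("MCL_AB", "MCL_PB")) {
      expect_lt(sqrt(sum((b$origin - me)^2)), 10)
      expect_lt(b$insertion[3], 0)  # insertion on the medial ulna
    }
    if (b$complex %in% c("LUCL", "RCL"))
      expect_lt(sqrt(sum((b$origin - le)^2)), 10)
  }
  # MCL anterior bundle inserts near the sublime tubercle landmark
  ab <- Filter(function(b) b$complex == "MCL_AB", bundles)
  st <- geo$landmarks$ulna$sublime_tubercle
  for (b in ab) expect_lt(sqrt(sum((b$insertion - st)^2)), 8)
})

test_that("generation is a pure function of config and seed", {
  g1 <- generate_elbow(geometry_config(seed = 7))
  g2 <- generate_elbow(geometry_config(seed = 7))
  expect_identical(g1$contact_elements, g2$contact_elements)
  expect_identical(g1$atlas, g2$atlas)
  expect_identical(g1$bone_meshes$humerus$vertices,
                   g2$bone_meshes$humerus$vertices)
  g3 <- generate_elbow(geometry_config(seed = 8))
  expect_false(identical(g1$atlas, g3$atlas))
  # generation does not disturb the caller's RNG stream
  set.seed(5); a <- runif(1)
  set.seed(5); invisible(generate_elbow(geometry_config(seed = 9)))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("element count and areas are consistent with the articular area", {
  geo <- small_geo()
  # independent area oracle: triangle areas of the cartilage surface
  # meshes (built on a fine parametric grid, not from the elements)
  A <- sum(geo$cartilage_meshes$trochlea$face_areas) +
    sum(geo$cartilage_meshes$capitellum$face_areas)
  n <- length(geo$contact_elements)
  edge <- geo$config$element_edge
  expect_lt(abs(n - A / edge^2) / (A / edge^2), 0.10)
  expect_lt(abs(element_area_total(geo) - A) / A, 0.10)
  # normals are unit length, areas positive
  for (e in geo$contact_elements) {
    expect_equal(sqrt(sum(e$normal^2)), 1, tolerance = 1e-9)
    expect_gt(e$area, 0)
  }
})

test_that("ligament attachments lie on (within 1 mm of) their host bone", {
  geo <- small_geo()
  for (b in geo$atlas$bundles) {
    d_o <- point_surface_signed_distance(
      b$origin, geo$bone_meshes[[b$origin_body]])$distance
    d_i <- point_surface_signed_distance(
      b$insertion, geo$bone_meshes[[b$insertion_body]])$distance
    expect_lt(abs(d_o), 1, label = paste(b$name, "origin"))
    expect_lt(abs(d_i), 1, label = paste(b$name, "insertion"))
  }
})

test_that("flat-patch discretization recovers the exact grid", {
  patch <- flat_patch_mesh(20, 20, 20, 20)
  els <- discretize_cartilage(patch, 5)
  expect_equal(length(els), 16)
  areas <- vapply(els, function(e) e$area, 0)
  # principal-axis binning can trade a sliver triangle across a cell edge
  expect_equal(sort(areas), rep(25, 16), tolerance = 0.05)
  expect_equal(sum(areas), 400, tolerance = 1e-9)
  # all element areas within the tiling tolerance
  expect_true(all(areas >= 0.5 * 25 & areas <= 2 * 25))
})

test_that("curved-surface discretization conserves area within 5%", {
  r <- 15; L <- 30; ang <- pi
  cyl <- cylinder_sector_mesh(r, L, ang, na = 60, nz = 30)
  els <- discretize_cartilage(cyl, 5)
  analytic <- ang * r * L  # sector of 2 pi r L
  expect_lt(abs(sum(vapply(els, function(e) e$area, 0)) - analytic) /
              analytic, 0.05)
  areas <- vapply(els, function(e) e$area, 0)
  expect_true(all(areas >= 0.5 * 25 & areas <= 2 * 25))
})

test_that("surfaces smaller than one element collapse with a warning", {
  tiny <- flat_patch_mesh(3, 3, 3, 3)
  expect_warning(els <- discretize_cartilage(tiny, 5), "single element")
  expect_equal(length(els), 1)
  expect_equal(els[[1]]$area, 9, tolerance = 1e-9)
})

test_that("STL and OBJ round-trip the meshes", {
  geo <- small_geo()
  m <- geo$cartilage_meshes$trochlea
  tf <- tempfile(fileext = ".stl")
  write_stl(m, tf, binary = TRUE)
  m2 <- read_stl(tf, open = TRUE)
  expect_equal(sum(m2$face_areas), sum(m$face_areas), tolerance = 1e-4)
  expect_equal(nrow(m2$faces), nrow(m$faces))
  ta <- tempfile(fileext = ".stl")
  write_stl(m, ta, binary = FALSE)
  m3 <- read_stl(ta, open = TRUE)
  expect_equal(sum(m3$face_areas), sum(m$face_areas), tolerance = 1e-6)
  to <- tempfile(fileext = ".obj")
  write_obj(m, to)
  m4 <- read_obj(to, open = TRUE)
  expect_equal(m4$vertices, m$vertices, tolerance = 1e-7,
               ignore_attr = TRUE)
  expect_equal(m4$faces, m$faces, ignore_attr = TRUE)
})

test_that("atlas JSON document round-trips", {
  geo <- small_geo()
  tf <- tempfile(fileext = ".json")
  write_atlas_json(geo, tf)
  back <- read_atlas_json(tf)
  expect_equal(length(back$atlas$bundles), 14)
  for (i in seq_along(geo$atlas$bundles)) {
    a <- geo$atlas$bundles[[i]]; b <- back$atlas$bundles[[i]]
    expect_equal(a$name, b$name)
    expect_equal(a$origin, b$origin, tolerance = 1e-12)
    expect_equal(a$insertion, b$insertion, tolerance = 1e-12)
    expect_equal(a$l0, b$l0, tolerance = 1e-12)
    expect_equal(a$k, b$k)
    expect_equal(length(a$wrap_primitives), length(b$wrap_primitives))
  }
  expect_equal(back$landmarks$humerus$medial_epicondyle,
               geo$landmarks$humerus$medial_epicondyle, tolerance = 1e-12)
})

test_that("geometry directory export reads back losslessly", {
  geo <- small_geo()
  d <- file.path(tempdir(), "geo_export")
  write_geometry(geo, d)
  back <- read_geometry(d)
  expect_setequal(names(back$bone_meshes),
                  c("humerus", "ulna", "radius", "hand"))
  expect_setequal(names(back$cartilage_meshes),
                  c("trochlea", "capitellum", "sigmoid_notch", "radial_head"))
  expect_equal(length(back$atlas$bundles), 14)
  # repeated export with the same seed is byte-identical
  d2 <- file.path(tempdir(), "geo_export2")
  write_geometry(generate_elbow(geometry_config(seed = 1)), d2)
  for (f in list.files(d)) {
    expect_equal(unname(tools::md5sum(file.path(d, f))),
                 unname(tools::md5sum(file.path(d2, f))), label = f)
  }
})
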