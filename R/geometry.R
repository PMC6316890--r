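#' Synthetic parametric elbow geometry
#'
#' Generates a complete seeded right-arm elbow: distal humerus
#' (grooved-spool trochlea + spherical capitellum), proximal ulna with a
#' congruent concave sigmoid notch, radial head with a concave spherical
#' dish, cartilage layers, discretized humeral contact elements, a
#' 14-bundle ligament attachment atlas and anatomical landmarks. The
#' geometry stands in for subject-specific image-derived bone surfaces
#' while preserving the structural features the deficiency analysis needs:
#' high ulnohumeral congruence, a medial constraint dominated by the MCL,
#' and a lateral column (radiocapitellar contact + LUCL/RCL) that acts as
#' the pivot when the medial side opens.
#'
#' Frames and units: millimetres, Newtons, seconds, MPa; right-handed
#' world frame with +x anterior, +y superior, +z lateral (right arm).
#' Each body frame coincides with the world frame at the reference pose
#' (initial flexion angle), with body origins at: humerus - trochlea
#' groove axis (elbow centre); ulna - sigmoid notch axis; radius - dish
#' sphere centre; hand - wrist centre.
#'
#' A deliberate anatomical feature is the slight spiral of the trochlear
#' groove in deep flexion (`groove_spiral`, mm of axial groove travel per
#' radian of arc beyond `spiral_onset`). The congruent notch then has to
#' track laterally as flexion deepens; with the hand held on the plate
#' this loads the medial soft tissues exactly as a passive pronated
#' flexion does in vitro - no external valgus torque is ever applied.
#'
#' @name synthetic-geometry
NULL

#' Geometry configuration
#'
#' All dimensions in mm, angles in degrees. Defaults give an adult-male
#' scale elbow. The same `seed` and configuration always regenerate a
#' bitwise-identical geometry.
#'
#' @param trochlea_radius subchondral trochlea lip radius.
#' @param trochlea_groove_depth depth of the central groove below the lips.
#' @param capitellum_radius subchondral capitellum radius.
#' @param sigmoid_notch_wrap_angle angular extent of the sigmoid notch
#'   about the flexion axis, degrees (in (90, 200)).
#' @param radial_head_radius radial head disc radius (wrap surface for the
#'   annular ligament and LUCL).
#' @param cartilage_thickness_uh combined ulnohumeral cartilage thickness.
#' @param cartilage_thickness_rh combined radiohumeral cartilage thickness.
#' @param element_edge target contact element edge length (elements are
#'   approximately `element_edge` x `element_edge`).
#' @param humerus_length,ulna_length,radius_length segment lengths.
#' @param initial_flexion initial elbow flexion angle, degrees.
#' @param carrying_angle valgus deviation of the forearm axis from the
#'   humeral long axis, degrees.
#' @param groove_spiral axial (lateral) travel of the trochlear groove per
#'   radian of arc beyond `spiral_onset`, mm/rad.
#' @param spiral_onset flexion-arc angle (degrees) at which the groove
#'   spiral begins.
#' @param groove_spiral_max saturation of the total groove travel, mm
#'   (the oblique track straightens again toward terminal flexion).
#' @param clearance resting articular clearance between cartilage
#'   surfaces, mm.
#' @param ligament_k named per-bundle stiffness parameters (N per unit
#'   strain) for the five complexes. Calibration values chosen so the
#'   intact simulation produces complex peak strains in the 0.10-0.50
#'   band; not tissue ground truth.
#' @param prestrain named per-complex reference-pose engineering strain
#'   used to set zero-load lengths from the generated geometry (negative
#'   values mean slack at the reference pose).
#' @param interosseous logical: include the interosseous membrane /
#'   distal radioulnar tie force elements.
#' @param seed integer RNG seed for the (small) anatomical jitter.
#' @return object of class `geometry_config`.
#' @export
geometry_config <- function(trochlea_radius = 12,
                            trochlea_groove_depth = 1.5,
                            capitellum_radius = 11,
                            sigmoid_notch_wrap_angle = 190,
                            radial_head_radius = 11.5,
                            cartilage_thickness_uh = 4,
                            cartilage_thickness_rh = 4.8,
                            element_edge = 5,
                            humerus_length = 300,
                            ulna_length = 260,
                            radius_length = 250,
                            initial_flexion = 49,
                            carrying_angle = 12,
                            groove_spiral = 3.5,
                            spiral_onset = 80,
                            groove_spiral_max = 4,
                            clearance = 0.15,
                            ligament_k = c(MCL_AB = 480, MCL_PB = 45,
                                           LUCL = 250, RCL = 120,
                                           annular = 150),
                            prestrain = c(MCL_AB = 0.01, MCL_PB = -0.05,
                                          LUCL = 0.05, RCL = 0.05,
                                          annular = 0.02),
                            interosseous = TRUE,
                            seed = 1L) {
  cfg <- list(trochlea_radius = trochlea_radius,
              trochlea_groove_depth = trochlea_groove_depth,
              capitellum_radius = capitellum_radius,
              sigmoid_notch_wrap_angle = sigmoid_notch_wrap_angle,
              radial_head_radius = radial_head_radius,
              cartilage_thickness_uh = cartilage_thickness_uh,
              cartilage_thickness_rh = cartilage_thickness_rh,
              element_edge = element_edge,
              humerus_length = humerus_length,
              ulna_length = ulna_length,
              radius_length = radius_length,
              initial_flexion = initial_flexion,
              carrying_angle = carrying_angle,
              groove_spiral = groove_spiral,
              spiral_onset = spiral_onset,
              groove_spiral_max = groove_spiral_max,
              clearance = clearance,
              ligament_k = ligament_k,
              prestrain = prestrain,
              interosseous = isTRUE(interosseous),
              seed = as.integer(seed))
  pos_fields <- c("trochlea_radius", "trochlea_groove_depth",
                  "capitellum_radius", "radial_head_radius",
                  "cartilage_thickness_uh", "cartilage_thickness_rh",
                  "element_edge", "humerus_length", "ulna_length",
                  "radius_length", "clearance")
  for (f in pos_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop("invalid geometry configuration: field '", f,
           "' must be a positive number")
  }
  if (!is.numeric(cfg$sigmoid_notch_wrap_angle) ||
      cfg$sigmoid_notch_wrap_angle <= 90 ||
      cfg$sigmoid_notch_wrap_angle >= 200)
    stop("invalid geometry configuration: field 'sigmoid_notch_wrap_angle' ",
         "must lie in (90, 200) degrees")
  if (!all(LIG_COMPLEXES %in% names(cfg$ligament_k)))
    stop("invalid geometry configuration: field 'ligament_k' must name all ",
         "five complexes")
  if (!all(LIG_COMPLEXES %in% names(cfg$prestrain)))
    stop("invalid geometry configuration: field 'prestrain' must name all ",
         "five complexes")
  structure(cfg, class = "geometry_config")
}

# forearm-plane direction: alpha = 0 points inferior (-y), alpha = 90 deg
# anterior (+x). This is the arc coordinate of flexion.
dir_alpha <- function(alpha) c(sin(alpha), -cos(alpha), 0)

# groove axial position as a function of arc angle (radians): fixed until
# spiral_onset, then ramps in C1 fashion with slope `sigma` mm/rad.
groove_center_z <- function(alpha, cfg) {
  on <- deg2rad(cfg$spiral_onset)
  w <- 0.35  # blend width, rad
  x <- alpha - on
  ramp <- ifelse(x <= 0, 0, ifelse(x < w, x^2 / (2 * w), x - w / 2))
  shift <- cfg$groove_spiral * ramp
  cap <- cfg$groove_spiral_max %||% Inf
  # smooth saturation of the track travel toward terminal flexion
  if (is.finite(cap)) shift <- cap * tanh(shift / cap)
  -13 + shift
}

# cartilage-surface trochlea profile: radius about the flexion axis as a
# function of axial offset from the groove centre. Returns value and
# d(radius)/d(offset).
trochlea_profile <- function(zoff, cfg) {
  Rt <- cfg$trochlea_radius + 0.5 * cfg$cartilage_thickness_uh
  g <- cfg$trochlea_groove_depth
  w <- 20
  inside <- abs(zoff) <= w / 2
  r <- ifelse(inside, Rt - (g / 2) * (1 + cos(2 * pi * zoff / w)), Rt)
  dr <- ifelse(inside, (g / 2) * sin(2 * pi * zoff / w) * (2 * pi / w), 0)
  list(r = r, dr = dr)
}

#' Generate the synthetic elbow
#'
#' @param config a [geometry_config()].
#' @return object of class `elbow_geometry`: reference body poses, analytic
#'   articular surface parameters, contact elements, ligament atlas with
#'   zero-load lengths set at the reference pose, muscle anchors, segment
#'   masses, landmarks and triangulated bone/cartilage meshes.
#' @examples
#' geo <- generate_elbow(geometry_config(seed = 1))
#' length(geo$atlas$bundles)  # 14
#' @export
generate_elbow <- function(config) {
  if (!inherits(config, "geometry_config"))
    config <- do.call(geometry_config, as.list(config))
  cfg <- config
  with_seed(cfg$seed, {
    phi0 <- deg2rad(cfg$initial_flexion)
    cv <- deg2rad(cfg$carrying_angle)
    # forearm axis at reference (carrying angle tilts it laterally)
    d0 <- c(sin(phi0) * cos(cv), -cos(phi0) * cos(cv), sin(cv))
    af <- c(cos(phi0), sin(phi0), 0)          # forearm "anterior" axis
    z_cap <- 12                                # capitellum centre, lateral
    R_capc <- cfg$capitellum_radius + 0.5 * cfg$cartilage_thickness_rh
    R_dish <- R_capc + cfg$clearance
    Lw <- cfg$ulna_length - 25                 # elbow-to-wrist distance
    wrist <- Lw * d0

    jit <- function(s) stats::runif(1, -s, s)
    # small seeded anatomical scatter on attachment anchors
    sc <- 0.5

    # ---- contact surface (analytic) parameters --------------------------
    surfaces <- list(
      trochlea = list(z_span = 20, alpha_range = deg2rad(c(-30, 200)),
                      groove_width = 20),
      notch = list(center_z = -13, half_span = 11,
                   wrap_half = deg2rad(cfg$sigmoid_notch_wrap_angle / 2),
                   sector_center = phi0, clearance = cfg$clearance),
      capitellum = list(center = c(0, 0, z_cap), radius = R_capc,
                        alpha_range = deg2rad(c(-30, 200)),
                        beta_half = deg2rad(42)),
      dish = list(radius = R_dish, axis = d0, cone_half = deg2rad(40))
    )

    # ---- contact elements (parametric discretization) -------------------
    elements <- list()
    eid <- 0L
    edge <- cfg$element_edge
    # trochlea band
    tr <- surfaces$trochlea
    r_mid <- trochlea_profile(0, cfg)$r - cfg$trochlea_groove_depth / 2
    arc <- (tr$alpha_range[2] - tr$alpha_range[1]) * r_mid
    ncol_t <- max(1L, round(arc / edge))
    dalpha <- (tr$alpha_range[2] - tr$alpha_range[1]) / ncol_t
    nrow_t <- max(1L, round(tr$z_span / edge))
    dz <- tr$z_span / nrow_t
    for (i in seq_len(ncol_t)) {
      a <- tr$alpha_range[1] + (i - 0.5) * dalpha
      zg <- groove_center_z(a, cfg)
      for (j in seq_len(nrow_t)) {
        zo <- -tr$z_span / 2 + (j - 0.5) * dz
        pr <- trochlea_profile(zo, cfg)
        u <- dir_alpha(a)
        ctr <- pr$r * u + c(0, 0, zg + zo)
        # outward normal of r = f(z): radial minus slope term
        n <- unitize(u - c(0, 0, pr$dr))
        area <- pr$r * dalpha * dz * sqrt(1 + pr$dr^2)
        eid <- eid + 1L
        elements[[eid]] <- contact_element(eid, ctr, n, area,
                                           map_uv = c(a * r_mid, zg + zo),
                                           region = "trochlea")
      }
    }
    # capitellum band
    cp <- surfaces$capitellum
    ncol_c <- max(1L, round((cp$alpha_range[2] - cp$alpha_range[1]) *
                              cp$radius / edge))
    dac <- (cp$alpha_range[2] - cp$alpha_range[1]) / ncol_c
    nrow_c <- max(1L, round(2 * cp$beta_half * cp$radius / edge))
    dbc <- 2 * cp$beta_half / nrow_c
    for (i in seq_len(ncol_c)) {
      a <- cp$alpha_range[1] + (i - 0.5) * dac
      for (j in seq_len(nrow_c)) {
        b <- -cp$beta_half + (j - 0.5) * dbc
        v <- cos(b) * dir_alpha(a) + sin(b) * c(0, 0, 1)
        ctr <- cp$center + cp$radius * v
        area <- cp$radius^2 * cos(b) * dac * dbc
        eid <- eid + 1L
        elements[[eid]] <- contact_element(eid, ctr, v, area,
                                           map_uv = c(a * cp$radius,
                                                      z_cap + cp$radius * sin(b)),
                                           region = "capitellum")
      }
    }

    # ---- landmarks ------------------------------------------------------
    me <- c(1, -2, -(21 + 4))        # medial epicondyle centre
    le <- c(0, 0, 21 + 3)            # lateral epicondyle centre
    landmarks <- list(
      humerus = list(medial_epicondyle = me, lateral_epicondyle = le,
                     elbow_center = c(0, 0, -13 + 6.5),
                     trochlea_center = c(0, 0, -13),
                     capitellum_center = cp$center,
                     humeral_head = c(0, cfg$humerus_length, 0)),
      ulna = list(notch_center = c(0, 0, -13),
                  olecranon_tip = -20 * d0 - 11 * af - 4 * c(0, 0, 1),
                  sublime_tubercle = NULL,  # filled below
                  radial_notch = 8 * d0 + c(0, 0, -1),
                  ulna_styloid = wrist + c(0, 0, -6)),
      radius = list(radial_head_center = c(0, 0, 0),
                    radial_head_lateral = c(0, 0, cfg$radial_head_radius),
                    radial_styloid = wrist + c(0, 0, 4) - c(0, 0, z_cap)),
      hand = list(wrist_center = c(0, 0, 0),
                  third_metacarpal = 55 * d0)
    )

    # ---- ligament atlas -------------------------------------------------
    # helper: point at radius `rad` from the flexion axis at arc angle
    # `alpha`, axial position z (all humeral side)
    axpt <- function(rad, alpha, z) rad * dir_alpha(alpha) + c(0, 0, z)
    kv <- cfg$ligament_k; pv <- cfg$prestrain
    bundles <- list()
    add <- function(b) bundles[[length(bundles) + 1L]] <<- b

    # MCL anterior bundle: medial epicondyle (anterior-inferior of axis)
    # to the sublime tubercle on the medial coronoid
    sub_tub <- axpt(15, phi0 + deg2rad(30), -14)
    landmarks$ulna$sublime_tubercle <- sub_tub
    for (i in 1:3) {
      da <- deg2rad(c(-28, 0, 28)[i])
      org <- axpt(4.5, deg2rad(95) + da * 0.4, -24 + jit(sc))
      ins <- axpt(15 + jit(sc), phi0 + deg2rad(30) + da, -14 + (i - 2) * 3)
      add(ligament_bundle(paste0("MCL_AB_", i), "MCL_AB", "humerus", org,
                          "ulna", ins, k = kv[["MCL_AB"]]))
    }
    # MCL posterior bundle: epicondyle (posterior-inferior) to medial
    # olecranon
    for (i in 1:3) {
      da <- deg2rad(c(-24, 0, 24)[i])
      org <- axpt(5, deg2rad(-60) + da * 0.4, -24 + jit(sc))
      ins <- axpt(14 + jit(sc), phi0 - deg2rad(55) + da, -16 + (i - 2) * 3)
      add(ligament_bundle(paste0("MCL_PB_", i), "MCL_PB", "humerus", org,
                          "ulna", ins, k = kv[["MCL_PB"]]))
    }
    # radial head wrap surfaces (fixed to the radius): ligaments ride in a
    # groove slightly inside the head rim
    r_wrap <- 0.8 * cfg$radial_head_radius
    head_cyl <- wrap_cylinder("radius", c(0, 0, 0), d0, r_wrap)
    head_sph <- wrap_sphere("radius", c(0, 0, 0), r_wrap)
    # LUCL: lateral epicondyle, wrapping the radial head, to the
    # supinator crest of the ulna
    for (i in 1:3) {
      da <- deg2rad(c(-10, 0, 10)[i])
      org <- axpt(4.5, deg2rad(30) + da, 23 + jit(sc))
      ins <- 32 * d0 + 7 * dir_alpha(phi0 - deg2rad(80)) +
        c(0, 0, -3 + (i - 2) * 1.5 + jit(sc))
      add(ligament_bundle(paste0("LUCL_", i), "LUCL", "humerus", org,
                          "ulna", ins, k = kv[["LUCL"]],
                          wrap_primitives = list(head_sph)))
    }
    # RCL: lateral epicondyle to the annular region of the ulna (straight)
    for (i in 1:3) {
      da <- deg2rad(c(-10, 0, 10)[i])
      org <- axpt(4, deg2rad(60) + da, 23 + jit(sc))
      ins <- 12 * d0 + 8 * dir_alpha(phi0 + deg2rad(45)) +
        c(0, 0, -2 + (i - 2) * 1.5 + jit(sc))
      add(ligament_bundle(paste0("RCL_", i), "RCL", "humerus", org,
                          "ulna", ins, k = kv[["RCL"]]))
    }
    # annular ligament: anterior rim of the radial notch around the radial
    # head to the posterior rim (both anchors on the ulna)
    for (i in 1:2) {
      s <- c(1, -1)[i]
      org <- 6 * d0 + s * 9 * af + c(0, 0, -1 + jit(sc))
      ins <- 6 * d0 - s * 9 * af + c(0, 0, -1 + jit(sc))
      add(ligament_bundle(paste0("annular_", i), "annular", "ulna", org,
                          "ulna", ins, k = kv[["annular"]],
                          wrap_primitives = list(head_cyl)))
    }
    atlas <- structure(list(bundles = bundles, scenario = "intact"),
                       class = "ligament_atlas")

    # ---- reference poses, masses, muscles ------------------------------
    bodies <- list(
      humerus = list(position = c(0, 0, 0), R = diag(3)),
      ulna = list(position = c(0, 0, 0), R = diag(3)),
      radius = list(position = cp$center, R = diag(3)),
      hand = list(position = wrist, R = diag(3))
    )
    masses <- list(
      ulna = list(mass = 0.80, com = 0.40 * Lw * d0 + c(0, 0, -3)),
      radius = list(mass = 0.40, com = 0.45 * Lw * d0 - cp$center / 2),
      hand = list(mass = 0.45, com = c(0, 0, 0))
    )
    muscles <- list(
      triceps = list(tension = 40, origin_body = "humerus",
                     origin = c(-15, 130, 0), insertion_body = "ulna",
                     insertion = -20 * d0 - 11 * af + c(0, 0, -5)),
      brachialis = list(tension = 20, origin_body = "humerus",
                        origin = c(14, 70, 0), insertion_body = "ulna",
                        insertion = 28 * d0 + 9 * af + c(0, 0, -6))
    )
    membrane <- if (cfg$interosseous) list(
      list(name = "interosseous_central", body_a = "ulna",
           point_a = 0.45 * Lw * d0 + c(0, 0, -2), body_b = "radius",
           point_b = 0.55 * Lw * d0 - cp$center + c(0, 0, 2),
           k = 30, rest = NULL),  # rest length set below at reference
      list(name = "distal_radioulnar", body_a = "ulna",
           point_a = wrist + c(0, 0, -6), body_b = "radius",
           point_b = wrist + c(0, 0, 2) - cp$center,
           k = 30, rest = NULL)
    ) else list()

    geo <- structure(list(
      config = cfg, phi0 = phi0, d0 = d0, af = af, wrist = wrist,
      surfaces = surfaces, contact_elements = elements,
      atlas = atlas, bodies = bodies, masses = masses, muscles = muscles,
      membrane = membrane, landmarks = landmarks,
      bone_meshes = NULL, cartilage_meshes = NULL),
      class = "elbow_geometry")

    # zero-load lengths from the reference pose
    geo$atlas <- set_zero_load_lengths(geo, prestrain = pv)
    # membrane rest lengths = reference lengths
    geo$membrane <- lapply(geo$membrane, function(m) {
      pa <- body_point_world(geo, m$body_a, m$point_a, reference = TRUE)
      pb <- body_point_world(geo, m$body_b, m$point_b, reference = TRUE)
      m$rest <- sqrt(sum((pa - pb)^2))
      m
    })
    geo$bone_meshes <- build_bone_meshes(geo)
    geo$cartilage_meshes <- build_cartilage_meshes(geo)
    geo
  })
}

#' World position of a body-frame point
#' @param geo an `elbow_geometry`.
#' @param body body name.
#' @param p body-frame point.
#' @param reference use the reference pose (`TRUE`) stored in the geometry.
#' @param poses optional named list of poses `list(position, R)` overriding
#'   the reference.
#' @keywords internal
body_point_world <- function(geo, body, p, reference = TRUE, poses = NULL) {
  po <- if (is.null(poses)) geo$bodies[[body]] else poses[[body]]
  po$position + as.numeric(po$R %*% p)
}

# set l0 for every bundle from the reference pose and per-complex prestrain
set_zero_load_lengths <- function(geo, prestrain) {
  atlas <- geo$atlas
  atlas$bundles <- lapply(atlas$bundles, function(b) {
    rt <- bundle_route(geo, b, poses = NULL)
    b$l0 <- rt$length / (1 + prestrain[[b$complex]])
    b
  })
  atlas
}

#' Route a bundle at given poses
#'
#' Transforms endpoints and wrap primitives to world coordinates and calls
#' [wrap_route()].
#' @param geo an `elbow_geometry`.
#' @param bundle a [ligament_bundle()].
#' @param poses named list of body poses (`NULL` = reference).
#' @return the [wrap_route()] result plus world endpoints.
#' @export
bundle_route <- function(geo, bundle, poses = NULL) {
  a <- body_point_world(geo, bundle$origin_body, bundle$origin, poses = poses)
  b <- body_point_world(geo, bundle$insertion_body, bundle$insertion,
                        poses = poses)
  prims <- lapply(bundle$wrap_primitives, function(pr) {
    po <- if (is.null(poses)) geo$bodies[[pr$body]] else poses[[pr$body]]
    prw <- pr
    prw$center <- po$position + as.numeric(po$R %*% pr$center)
    if (!is.null(pr$axis)) prw$axis <- as.numeric(po$R %*% pr$axis)
    prw
  })
  rt <- wrap_route(a, b, prims)
  rt$origin_world <- a
  rt$insertion_world <- b
  rt
}

# ---- meshes -------------------------------------------------------------

# triangulate a parametric grid of points (nu x nv x 3 array)
grid_to_mesh <- function(P, open = TRUE) {
  nu <- dim(P)[1]; nv <- dim(P)[2]
  V <- matrix(aperm(P, c(1, 2, 3)), nu * nv, 3)
  idx <- function(i, j) (j - 1) * nu + i
  faces <- list()
  for (j in seq_len(nv - 1)) for (i in seq_len(nu - 1)) {
    faces[[length(faces) + 1L]] <- c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1))
    faces[[length(faces) + 1L]] <- c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
  }
  Fc <- do.call(rbind, faces)
  # drop degenerate triangles (grid seams and poles)
  a <- V[Fc[, 1], , drop = FALSE]; b <- V[Fc[, 2], , drop = FALSE]
  c_ <- V[Fc[, 3], , drop = FALSE]
  cr <- cbind((b[, 2] - a[, 2]) * (c_[, 3] - a[, 3]) - (b[, 3] - a[, 3]) * (c_[, 2] - a[, 2]),
              (b[, 3] - a[, 3]) * (c_[, 1] - a[, 1]) - (b[, 1] - a[, 1]) * (c_[, 3] - a[, 3]),
              (b[, 1] - a[, 1]) * (c_[, 2] - a[, 2]) - (b[, 2] - a[, 2]) * (c_[, 1] - a[, 1]))
  keep <- sqrt(rowSums(cr^2)) > 1e-9
  tri_surface(V, Fc[keep, , drop = FALSE], open = open)
}

mesh_concat <- function(...) {
  ms <- list(...)
  V <- NULL; Fc <- NULL; off <- 0L
  for (m in ms) {
    V <- rbind(V, m$vertices)
    Fc <- rbind(Fc, m$faces + off)
    off <- off + nrow(m$vertices)
  }
  tri_surface(V, Fc, open = any(vapply(ms, function(m) m$open, TRUE)))
}

mesh_sphere <- function(center, radius, n = 12) {
  th <- seq(0, pi, length.out = n)
  ph <- seq(0, 2 * pi, length.out = 2 * n)
  P <- array(0, c(length(th), length(ph), 3))
  for (i in seq_along(th)) for (j in seq_along(ph)) {
    P[i, j, ] <- center + radius * c(sin(th[i]) * cos(ph[j]),
                                     cos(th[i]),
                                     sin(th[i]) * sin(ph[j]))
  }
  grid_to_mesh(P, open = TRUE)
}

mesh_tube <- function(p0, p1, radius, n = 14) {
  ax <- unitize(p1 - p0)
  e1 <- perp_unit_vec(ax); e2 <- crossv(ax, e1)
  ph <- seq(0, 2 * pi, length.out = n)
  ts <- seq(0, 1, length.out = 8)
  P <- array(0, c(length(ts), length(ph), 3))
  for (i in seq_along(ts)) for (j in seq_along(ph)) {
    P[i, j, ] <- p0 + ts[i] * (p1 - p0) +
      radius * (cos(ph[j]) * e1 + sin(ph[j]) * e2)
  }
  grid_to_mesh(P, open = TRUE)
}

# humeral articular cartilage surface mesh (trochlea + capitellum bands)
trochlea_cart_mesh <- function(geo, nu = 40, nv = 10) {
  cfg <- geo$config; tr <- geo$surfaces$trochlea
  al <- seq(tr$alpha_range[1], tr$alpha_range[2], length.out = nu)
  zo <- seq(-tr$z_span / 2, tr$z_span / 2, length.out = nv)
  P <- array(0, c(nu, nv, 3))
  for (i in seq_len(nu)) {
    zg <- groove_center_z(al[i], cfg)
    u <- dir_alpha(al[i])
    for (j in seq_len(nv)) {
      pr <- trochlea_profile(zo[j], cfg)
      P[i, j, ] <- pr$r * u + c(0, 0, zg + zo[j])
    }
  }
  grid_to_mesh(P)
}

capitellum_cart_mesh <- function(geo, nu = 36, nv = 8) {
  cp <- geo$surfaces$capitellum
  al <- seq(cp$alpha_range[1], cp$alpha_range[2], length.out = nu)
  be <- seq(-cp$beta_half, cp$beta_half, length.out = nv)
  P <- array(0, c(nu, nv, 3))
  for (i in seq_len(nu)) for (j in seq_len(nv)) {
    v <- cos(be[j]) * dir_alpha(al[i]) + sin(be[j]) * c(0, 0, 1)
    P[i, j, ] <- cp$center + cp$radius * v
  }
  grid_to_mesh(P)
}

notch_cart_mesh <- function(geo, nu = 30, nv = 10) {
  cfg <- geo$config; no <- geo$surfaces$notch
  al <- seq(no$sector_center - no$wrap_half, no$sector_center + no$wrap_half,
            length.out = nu)
  zo <- seq(-no$half_span, no$half_span, length.out = nv)
  P <- array(0, c(nu, nv, 3))
  for (i in seq_len(nu)) for (j in seq_len(nv)) {
    rr <- notch_radius(zo[j], cfg)
    P[i, j, ] <- rr * dir_alpha(al[i]) + c(0, 0, no$center_z + zo[j])
  }
  grid_to_mesh(P)
}

dish_cart_mesh <- function(geo, nu = 24, nv = 8) {
  di <- geo$surfaces$dish
  ax <- di$axis
  e1 <- perp_unit_vec(ax); e2 <- crossv(ax, e1)
  th <- seq(0, di$cone_half, length.out = nv)
  ph <- seq(0, 2 * pi, length.out = nu)
  P <- array(0, c(nu, nv, 3))
  for (i in seq_len(nu)) for (j in seq_len(nv)) {
    v <- cos(th[j]) * ax + sin(th[j]) * (cos(ph[i]) * e1 + sin(ph[i]) * e2)
    P[i, j, ] <- di$radius * v
  }
  grid_to_mesh(P)
}

# notch profile radius at axial offset from its centre (congruent to the
# trochlea profile plus the articular clearance)
notch_radius <- function(zoff, cfg) {
  trochlea_profile(zoff, cfg)$r + cfg$clearance
}

build_cartilage_meshes <- function(geo) {
  list(trochlea = trochlea_cart_mesh(geo),
       capitellum = capitellum_cart_mesh(geo),
       sigmoid_notch = notch_cart_mesh(geo),
       radial_head = dish_cart_mesh(geo))
}

build_bone_meshes <- function(geo) {
  cfg <- geo$config
  lm <- geo$landmarks
  d0 <- geo$d0
  # enthesis knobs: a small sphere under every ligament attachment so the
  # anchors sit on the bone surface (centre pulled toward the bone core)
  enthesis <- function(body) {
    pts <- list()
    core_dir <- function(p) {
      if (body == "humerus") {
        epi <- if (p[3] < 0) lm$humerus$medial_epicondyle
        else lm$humerus$lateral_epicondyle
        v <- epi - p
        if (sqrt(sum(v^2)) < 1e-6) v <- c(0, 1, 0)
        unitize(v)
      } else {
        # toward the segment long axis through the body origin
        t_ <- sum(p * d0)
        ax <- t_ * d0
        v <- ax - p
        if (sqrt(sum(v^2)) < 1e-6) v <- c(0, 1, 0)
        unitize(v)
      }
    }
    for (b in geo$atlas$bundles) {
      if (b$origin_body == body) pts <- c(pts, list(b$origin))
      if (b$insertion_body == body) pts <- c(pts, list(b$insertion))
    }
    lapply(pts, function(p) mesh_sphere(p + 4 * core_dir(p), 4, n = 10))
  }
  # humerus: shaft tube + epicondylar spheres + articular core
  hum <- do.call(mesh_concat, c(list(
    mesh_tube(c(0, 14, 0), c(0, cfg$humerus_length, 0), 13),
    mesh_sphere(lm$humerus$medial_epicondyle, 6),
    mesh_sphere(lm$humerus$lateral_epicondyle, 6),
    trochlea_cart_mesh(geo), capitellum_cart_mesh(geo)),
    enthesis("humerus")))
  # ulna: shaft + notch + attachment tubercles
  uln <- do.call(mesh_concat, c(list(
    mesh_tube(5 * d0, geo$wrist + c(0, 0, -6), 7),
    notch_cart_mesh(geo),
    mesh_sphere(lm$ulna$sublime_tubercle, 4),
    mesh_sphere(lm$ulna$olecranon_tip, 6)),
    enthesis("ulna")))
  # radius (body frame: origin at dish centre)
  rad <- do.call(mesh_concat, c(list(
    mesh_tube(6 * d0, geo$wrist + c(0, 0, 2) - geo$surfaces$capitellum$center, 6),
    dish_cart_mesh(geo),
    mesh_tube(-2 * d0, 6 * d0, cfg$radial_head_radius, n = 20)),
    enthesis("radius")))
  hnd <- mesh_tube(c(0, 0, 0), 80 * d0, 10)
  list(humerus = hum, ulna = uln, radius = rad, hand = hnd)
}

# ---- generic surface discretization ------------------------------------

#' Discretize a triangulated cartilage surface into contact elements
#'
#' Tiles an arbitrary triangulated patch into approximately
#' `element_edge` x `element_edge` elements: triangles are binned by
#' centroid on a regular grid in the surface's two principal directions,
#' bins smaller than half an element area are merged into their nearest
#' neighbour, and each element carries the area-weighted centroid, normal
#' and total triangle area of its bin, plus its 2D grid coordinate for
#' pressure-map rendering.
#'
#' @param surface a [tri_surface()].
#' @param element_edge target element edge length, mm.
#' @param region region label for the produced elements.
#' @return list of [contact_element()].
#' @export
discretize_cartilage <- function(surface, element_edge, region = "trochlea") {
  stopifnot(inherits(surface, "tri_surface"))
  if (!is.numeric(element_edge) || element_edge <= 0)
    stop("element_edge must be positive")
  cen <- surface$face_centers
  ar <- surface$face_areas
  nrm <- surface$face_normals
  # principal directions of the vertex cloud
  pc <- stats::prcomp(surface$vertices, center = TRUE, scale. = FALSE)
  uv <- cen %*% pc$rotation[, 1:2]
  total_area <- sum(ar)
  if (total_area <= element_edge^2) {
    warning("surface smaller than one element; returning a single element")
    n <- colSums(nrm * ar)
    return(list(contact_element(1L, colSums(cen * ar) / total_area,
                                n, total_area, map_uv = c(0, 0),
                                region = region)))
  }
  gu <- floor((uv[, 1] - min(uv[, 1])) / element_edge)
  gv <- floor((uv[, 2] - min(uv[, 2])) / element_edge)
  key <- paste(gu, gv)
  bins <- split(seq_len(nrow(cen)), key)
  binfo <- lapply(bins, function(ix) {
    a <- sum(ar[ix])
    list(ix = ix, area = a,
         uv = colSums(uv[ix, , drop = FALSE] * ar[ix]) / a)
  })
  # merge undersized bins into a nearby adequately-sized neighbour,
  # preferring targets that stay within the 2x element-area tolerance
  amin <- 0.5 * element_edge^2
  amax <- 2 * element_edge^2
  big <- which(vapply(binfo, function(b) b$area >= amin, TRUE))
  if (!length(big)) big <- which.max(vapply(binfo, function(b) b$area, 0))
  small <- setdiff(seq_along(binfo), big)
  for (s in small) {
    duv <- vapply(binfo[big], function(b) sum((b$uv - binfo[[s]]$uv)^2), 0)
    fits <- vapply(binfo[big], function(b)
      b$area + binfo[[s]]$area <= amax, TRUE)
    cand <- if (any(fits)) big[fits][which.min(duv[fits])]
    else big[which.min(duv)]
    binfo[[cand]]$ix <- c(binfo[[cand]]$ix, binfo[[s]]$ix)
    binfo[[cand]]$area <- binfo[[cand]]$area + binfo[[s]]$area
  }
  binfo <- binfo[big]
  # near-silhouette cells of a curved patch can collect far more surface
  # than their projected footprint: split oversized bins recursively
  split_bin <- function(b, depth = 0) {
    if (b$area <= amax || length(b$ix) < 2 || depth > 6) return(list(b))
    u <- uv[b$ix, 1]; v <- uv[b$ix, 2]
    along_u <- (max(u) - min(u)) >= (max(v) - min(v))
    x <- if (along_u) u else v
    med <- stats::median(x)
    lo <- b$ix[x <= med]; hi <- b$ix[x > med]
    if (!length(lo) || !length(hi)) {
      ord <- order(x)
      half <- ceiling(length(ord) / 2)
      lo <- b$ix[ord[seq_len(half)]]; hi <- b$ix[ord[-seq_len(half)]]
      if (!length(hi)) return(list(b))
    }
    mk <- function(ix) list(ix = ix, area = sum(ar[ix]),
                            uv = colSums(uv[ix, , drop = FALSE] * ar[ix]) /
                              sum(ar[ix]))
    c(split_bin(mk(lo), depth + 1), split_bin(mk(hi), depth + 1))
  }
  binfo <- do.call(c, lapply(binfo, split_bin))
  out <- vector("list", length(binfo))
  for (i in seq_along(binfo)) {
    ix <- binfo[[i]]$ix
    a <- sum(ar[ix])
    ctr <- colSums(cen[ix, , drop = FALSE] * ar[ix]) / a
    n <- colSums(nrm[ix, , drop = FALSE] * ar[ix])
    out[[i]] <- contact_element(i, ctr, n, a, map_uv = binfo[[i]]$uv,
                                region = region)
  }
  out
}

#' Total articular element area of a geometry
#' @param geo an `elbow_geometry`.
#' @param region optional region filter.
#' @return total area, mm^2.
#' @export
element_area_total <- function(geo, region = NULL) {
  el <- geo$contact_elements
  if (!is.null(region)) el <- Filter(function(e) e$region == region, el)
  sum(vapply(el, function(e) e$area, 0))
}
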