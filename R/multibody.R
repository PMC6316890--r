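#' Multibody assembly and the passive-flexion solve
#'
#' The joint is driven by prescribing the humeral pose: the humerus is
#' attached to ground through a translational (prismatic) joint and its
#' head is displaced vertically downward (345 mm over 40 s by default).
#' The ulna and radius are free 6-DOF bodies; the hand is connected to the
#' radius by a spherical wrist joint (position eliminated, orientation
#' free) and to ground through a soft 6-DOF bushing representing the
#' plate. Free coordinates (15): ulna translation + rotation, radius
#' translation + rotation, hand rotation.
#'
#' The default solver is quasistatic continuation: at each drive increment
#' the total potential energy (contact + ligaments + muscles with constant
#' tension + gravity + bushing) is minimised over the free coordinates
#' with analytic gradients, i.e. a damped-Newton force balance. At the
#' 8.6 mm/s drive speed inertial and damping forces are negligible, so
#' dampers do not enter the statics; penetration and lengthening rates are
#' recovered by finite differences between accepted steps and the damping
#' contributions are included in the *reported* contact and ligament
#' forces. A dynamic mode (stiff implicit integration of the full
#' second-order equations, including the contact and ligament dampers) is
#' available for fidelity checks.
#'
#' @name multibody-sim
NULL

ROT_SCALE <- 100  # rotation coordinates are stored as (angle * ROT_SCALE)

#' Prescribed humeral-head motion drive
#'
#' @param total_displacement total vertical displacement, mm.
#' @param duration drive duration, s.
#' @param profile `"linear"` (constant rate) or `"smoothed"` (cubic ramp).
#' @param direction unit drive direction (default vertical downward).
#' @return object of class `motion_drive`.
#' @export
motion_drive <- function(total_displacement = 345, duration = 40,
                         profile = c("linear", "smoothed"),
                         direction = c(0, -1, 0)) {
  profile <- match.arg(profile)
  if (!is.numeric(duration) || duration <= 0) stop("duration must be > 0")
  if (total_displacement < 0) stop("total_displacement must be >= 0")
  structure(list(total_displacement = total_displacement,
                 duration = duration, profile = profile,
                 direction = unitize(direction)),
            class = "motion_drive")
}

#' Simulation configuration
#'
#' @param solver `"quasistatic"` (default) or `"dynamic"`.
#' @param n_steps number of drive increments.
#' @param tol residual generalized-force tolerance for an accepted
#'   quasistatic step (N, with torques scaled by 1/100 mm^-1).
#' @param max_flexion stop the run once this flexion angle (degrees) is
#'   reached.
#' @param max_step_halvings adaptive step-halving depth at non-convergence.
#' @param separation_bound joint separation (mm) beyond which a step is
#'   flagged as a dislocation candidate input (the scenario-level flag also
#'   requires a sustained loss of compartment contact).
#' @param seed integer seed recorded with the run.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(solver = c("quasistatic", "dynamic"),
                              n_steps = 160, tol = 1e-3, max_flexion = 135,
                              max_step_halvings = 6, separation_bound = 10,
                              seed = 1L) {
  solver <- match.arg(solver)
  if (!is.numeric(tol) || tol <= 0) stop("tol must be positive")
  if (n_steps < 2) stop("n_steps must be at least 2")
  structure(list(solver = solver, n_steps = as.integer(n_steps), tol = tol,
                 max_flexion = max_flexion,
                 max_step_halvings = max_step_halvings,
                 separation_bound = separation_bound, seed = as.integer(seed)),
            class = "simulation_config")
}

#' External loads
#'
#' @param muscle_tensions named vector of constant muscle tensions, N
#'   (names must match the geometry's muscle anchors).
#' @param gravity logical, include segment weights.
#' @param g gravitational acceleration, m/s^2.
#' @return object of class `external_loads`.
#' @export
external_loads <- function(muscle_tensions = c(triceps = 40, brachialis = 20),
                           gravity = TRUE, g = 9.81) {
  if (any(muscle_tensions < 0)) stop("muscle tensions must be >= 0")
  structure(list(muscle_tensions = muscle_tensions,
                 gravity = isTRUE(gravity), g = g),
            class = "external_loads")
}

#' Assemble the multibody system
#'
#' Collects geometry, (possibly sectioned) ligament atlas, contact
#' parameters, bushing and loads into a system object whose
#' `$force_model(poses)` evaluates the generalized force (negative energy
#' gradient) on the free coordinates, and which [run_flexion_sim()]
#' advances along the drive.
#'
#' @param geometry an `elbow_geometry` from [generate_elbow()].
#' @param atlas ligament atlas; defaults to the geometry's intact atlas.
#' @param contact named list with `uh` and `rh` [contact_parameters()].
#' @param loads an [external_loads()].
#' @param bushing list with `k_t` (N/mm, length 3), `k_r` (N mm/rad).
#' @return object of class `elbow_system`.
#' @export
assemble_system <- function(geometry, atlas = NULL,
                            contact = list(uh = contact_parameters(kc = 126),
                                           rh = contact_parameters(kc = 105)),
                            loads = external_loads(),
                            bushing = list(k_t = c(1, 1, 1), k_r = 5.73)) {
  stopifnot(inherits(geometry, "elbow_geometry"))
  if (is.null(atlas)) atlas <- geometry$atlas
  bodies <- c("humerus", "ulna", "radius", "hand")
  for (b in atlas$bundles) {
    if (!b$origin_body %in% bodies || !b$insertion_body %in% bodies)
      stop("assembly error: bundle '", b$name,
           "' references an unknown body")
    for (pr in b$wrap_primitives)
      if (!pr$body %in% bodies)
        stop("assembly error: wrap primitive references unknown body '",
             pr$body, "'")
  }
  for (m in geometry$muscles)
    if (!m$origin_body %in% bodies || !m$insertion_body %in% bodies)
      stop("assembly error: muscle references an unknown body")
  el <- geometry$contact_elements
  reg <- vapply(el, function(e) e$region, "")
  cent <- t(vapply(el, function(e) e$center, c(0, 0, 0)))
  area <- vapply(el, function(e) e$area, 0)
  sys <- structure(list(
    geometry = geometry, atlas = atlas, contact = contact, loads = loads,
    bushing = bushing,
    troch_idx = which(reg == "trochlea"), cap_idx = which(reg == "capitellum"),
    centers = cent, areas = area,
    wrist_local_radius = geometry$wrist - geometry$bodies$radius$position,
    hand_ref = geometry$bodies$hand$position,
    hand_R_ref = geometry$bodies$hand$R
  ), class = "elbow_system")
  sys$force_model <- function(poses) -energy_gradient(sys, poses)$gradient
  sys
}

# ---- poses <-> coordinates ---------------------------------------------

sys_reference_base <- function(sys) {
  g <- sys$geometry
  list(ulna = g$bodies$ulna, radius = g$bodies$radius,
       hand = g$bodies$hand)
}

q_from_base <- function(base) {
  c(base$ulna$position, 0, 0, 0, base$radius$position, 0, 0, 0, 0, 0, 0)
}

poses_from_q <- function(sys, q, base, humerus_position) {
  Ru <- rotvec_to_matrix(q[4:6] / ROT_SCALE) %*% base$ulna$R
  Rr <- rotvec_to_matrix(q[10:12] / ROT_SCALE) %*% base$radius$R
  Rh <- rotvec_to_matrix(q[13:15] / ROT_SCALE) %*% base$hand$R
  tr <- q[7:9]
  hand_pos <- tr + as.numeric(Rr %*% sys$wrist_local_radius)
  list(humerus = list(position = humerus_position, R = diag(3)),
       ulna = list(position = q[1:3], R = Ru),
       radius = list(position = tr, R = Rr),
       hand = list(position = hand_pos, R = Rh))
}

# left Jacobian of SO(3): exp(phi + dphi) ~ exp(Jl(phi) dphi) exp(phi)
so3_left_jacobian <- function(phi) {
  th <- sqrt(sum(phi^2))
  K <- skew3(phi)
  if (th < 1e-8) return(diag(3) + K / 2 + K %*% K / 6)
  diag(3) + (1 - cos(th)) / th^2 * K + (th - sin(th)) / th^3 * K %*% K
}

# energy_gradient() accumulates exact world-frame forces/torques at the
# current pose; this maps the rotational blocks to exact derivatives with
# respect to the finite rotation-vector coordinates q.
chart_correct_gradient <- function(g, q) {
  for (ix in list(4:6, 10:12, 13:15)) {
    J <- so3_left_jacobian(q[ix] / ROT_SCALE)
    g[ix] <- as.numeric(t(J) %*% g[ix])
  }
  g
}

smoothstep01 <- function(x) {
  s <- pmin(pmax(x, 0), 1)
  s * s * (3 - 2 * s)
}
d_smoothstep01 <- function(x) {
  ifelse(x > 0 & x < 1, 6 * x * (1 - x), 0)
}

wrap_pi <- function(a) ((a + pi) %% (2 * pi)) - pi

# ---- energy and gradient ------------------------------------------------
# Returns total potential energy and its gradient with respect to the 15
# free coordinates. With details = TRUE also returns per-element contact
# penetrations/forces and per-bundle lengths/forces (statics: no damping).
energy_gradient <- function(sys, poses, details = FALSE) {
  geo <- sys$geometry
  cfg <- geo$config
  E <- 0
  g <- numeric(15)
  t_u <- poses$ulna$position; R_u <- poses$ulna$R
  t_r <- poses$radius$position; R_r <- poses$radius$R
  t_h <- poses$humerus$position
  wrist_w <- poses$hand$position

  add_force <- function(body, p, f) {
    # accumulate gradient contribution of a world force f applied at world
    # point p on `body` (gradient = -generalized force)
    if (body == "ulna") {
      g[1:3] <<- g[1:3] - f
      g[4:6] <<- g[4:6] - crossv(p - t_u, f) / ROT_SCALE
    } else if (body == "radius") {
      g[7:9] <<- g[7:9] - f
      g[10:12] <<- g[10:12] - crossv(p - t_r, f) / ROT_SCALE
    } else if (body == "hand") {
      g[13:15] <<- g[13:15] - crossv(p - wrist_w, f) / ROT_SCALE
      g[7:9] <<- g[7:9] - f
      g[10:12] <<- g[10:12] - crossv(wrist_w - t_r, f) / ROT_SCALE
    } # humerus: prescribed, reactions carried by the ground joint
  }

  det_contact <- NULL
  det_lig <- NULL

  # ---- ulnohumeral contact (trochlea elements vs sigmoid notch) ---------
  no <- geo$surfaces$notch
  puh <- sys$contact$uh
  idx <- sys$troch_idx
  Xw <- sys$centers[idx, , drop = FALSE]
  Xw <- sweep(Xw, 2, t_h, "+")
  D <- sweep(Xw, 2, t_u, "-")
  Xu <- D %*% R_u
  r <- sqrt(Xu[, 1]^2 + Xu[, 2]^2)
  zoff <- Xu[, 3] - no$center_z
  alpha <- atan2(Xu[, 1], -Xu[, 2])
  adiff <- wrap_pi(alpha - no$sector_center)
  taper_a <- deg2rad(6); taper_z <- 1.5
  wa_x <- (no$wrap_half - abs(adiff)) / taper_a
  wz_x <- (no$half_span - abs(zoff)) / taper_z
  prof <- trochlea_profile(zoff, cfg)
  delta <- r - (prof$r + no$clearance)
  act <- which(delta > 0 & wa_x > 0 & wz_x > 0 & r > 1e-9)
  uh_delta_all <- delta; uh_w_all <- numeric(length(delta))
  if (length(act)) {
    wA <- smoothstep01(wa_x[act]); wZ <- smoothstep01(wz_x[act])
    W <- wA * wZ
    uh_w_all[act] <- W
    d_ <- delta[act]
    V <- puh$kc * d_^(puh$n + 1) / (puh$n + 1)
    Vp <- puh$kc * d_^puh$n
    E <- E + sum(W * V)
    # d(delta)/dx in ulna frame: radial unit minus profile slope axial term
    inv_r <- 1 / r[act]
    Gu <- cbind(Xu[act, 1] * inv_r, Xu[act, 2] * inv_r, -prof$dr[act])
    # window derivative terms
    dWa <- d_smoothstep01(wa_x[act]) / taper_a * (-sign(adiff[act])) * wZ
    # d(alpha)/dx in ulna frame
    Ga <- cbind(-Xu[act, 2], Xu[act, 1], 0) * inv_r^2
    dWz <- d_smoothstep01(wz_x[act]) / taper_z * (-sign(zoff[act])) * wA
    Gz <- cbind(0, 0, 1)
    Gtot_u <- Gu * (W * Vp) + Ga * (dWa * V) +
      matrix(Gz, length(act), 3, byrow = TRUE) * (dWz * V)
    Gw <- Gtot_u %*% t(R_u)   # dE/d(world element point) rows
    # force on ulna = +sum(Gw) ... gradient contributions:
    g[1:3] <- g[1:3] - colSums(Gw)
    Dm <- D[act, , drop = FALSE]
    tau <- c(sum(Gw[, 3] * Dm[, 2] - Gw[, 2] * Dm[, 3]),
             sum(Gw[, 1] * Dm[, 3] - Gw[, 3] * Dm[, 1]),
             sum(Gw[, 2] * Dm[, 1] - Gw[, 1] * Dm[, 2]))
    # tau = sum(Gw x D) = -sum(D x Gw); gradient for rotation is
    # +sum((dE/dx) . d x/d theta) with dx/dtheta_k = e_k x D
    g[4:6] <- g[4:6] - tau / ROT_SCALE
  }

  # ---- radiohumeral contact (capitellum elements vs radial dish) --------
  di <- geo$surfaces$dish
  prh <- sys$contact$rh
  idx2 <- sys$cap_idx
  Xw2 <- sweep(sys$centers[idx2, , drop = FALSE], 2, t_h, "+")
  D2 <- sweep(Xw2, 2, t_r, "-")
  Xr <- D2 %*% R_r
  rho <- sqrt(rowSums(Xr^2))
  axb <- di$axis
  cosang <- (Xr %*% axb)[, 1] / rho
  taper_c <- 0.08
  wc_x <- (cosang - cos(di$cone_half)) / taper_c
  delta2 <- rho - di$radius
  act2 <- which(delta2 > 0 & wc_x > 0)
  rh_delta_all <- delta2; rh_w_all <- numeric(length(delta2))
  if (length(act2)) {
    Wc <- smoothstep01(wc_x[act2])
    rh_w_all[act2] <- Wc
    d_ <- delta2[act2]
    V <- prh$kc * d_^(prh$n + 1) / (prh$n + 1)
    Vp <- prh$kc * d_^prh$n
    E <- E + sum(Wc * V)
    inv_rho <- 1 / rho[act2]
    Gd <- Xr[act2, , drop = FALSE] * inv_rho
    dWc <- d_smoothstep01(wc_x[act2]) / taper_c
    Gc <- (matrix(axb, length(act2), 3, byrow = TRUE) -
             Gd * cosang[act2]) * inv_rho
    Gtot_r <- Gd * (Wc * Vp) + Gc * (dWc * V)
    Gw2 <- Gtot_r %*% t(R_r)
    g[7:9] <- g[7:9] - colSums(Gw2)
    Dm <- D2[act2, , drop = FALSE]
    tau <- c(sum(Gw2[, 3] * Dm[, 2] - Gw2[, 2] * Dm[, 3]),
             sum(Gw2[, 1] * Dm[, 3] - Gw2[, 3] * Dm[, 1]),
             sum(Gw2[, 2] * Dm[, 1] - Gw2[, 1] * Dm[, 2]))
    g[10:12] <- g[10:12] - tau / ROT_SCALE
  }

  # ---- ligaments --------------------------------------------------------
  if (details) det_lig <- vector("list", length(sys$atlas$bundles))
  for (bi in seq_along(sys$atlas$bundles)) {
    b <- sys$atlas$bundles[[bi]]
    if (!isTRUE(b$active)) {
      if (details) det_lig[[bi]] <- data.frame(
        bundle = b$name, complex = b$complex, l = NA_real_,
        strain = NA_real_, force = 0, active = FALSE)
      next
    }
    rt <- bundle_route_poses(sys, b, poses, t_h)
    eps <- engineering_strain(rt$length, b$l0)
    f <- bundle_elastic_force(eps, b$k, b$eps_l)
    E <- E + lig_energy(eps, b$k, b$eps_l) * b$l0
    if (f > 0) {
      add_force(b$origin_body, rt$origin_world, f * rt$dir_origin)
      add_force(b$insertion_body, rt$insertion_world, f * rt$dir_insertion)
      if (isTRUE(rt$wrapped)) {
        pr <- b$wrap_primitives[[rt$primitive]]
        add_force(pr$body, rt$contact_center,
                  -f * (rt$dir_origin + rt$dir_insertion))
      }
    }
    if (details) det_lig[[bi]] <- data.frame(
      bundle = b$name, complex = b$complex, l = rt$length,
      strain = eps, force = f, active = TRUE)
  }

  # ---- muscles (constant tension) --------------------------------------
  for (mn in names(geo$muscles)) {
    m <- geo$muscles[[mn]]
    Tn <- sys$loads$muscle_tensions[[mn]]
    if (is.null(Tn) || is.na(Tn)) Tn <- m$tension
    a <- body_pt(poses, m$origin_body, m$origin, t_h)
    bpt <- body_pt(poses, m$insertion_body, m$insertion, t_h)
    L <- sqrt(sum((a - bpt)^2))
    E <- E + Tn * L
    u <- (a - bpt) / L
    add_force(m$insertion_body, bpt, Tn * u)
    add_force(m$origin_body, a, -Tn * u)
  }

  # ---- interosseous membrane ties --------------------------------------
  for (m in geo$membrane) {
    a <- body_pt(poses, m$body_a, m$point_a, t_h)
    bpt <- body_pt(poses, m$body_b, m$point_b, t_h)
    L <- sqrt(sum((a - bpt)^2))
    E <- E + 0.5 * m$k * (L - m$rest)^2
    if (L > 1e-9) {
      u <- (bpt - a) / L
      fm <- m$k * (L - m$rest)
      add_force(m$body_a, a, fm * u)
      add_force(m$body_b, bpt, -fm * u)
    }
  }

  # ---- gravity ----------------------------------------------------------
  if (sys$loads$gravity) {
    for (bn in names(geo$masses)) {
      ms <- geo$masses[[bn]]
      com <- body_pt(poses, bn, ms$com, t_h)
      w <- ms$mass * sys$loads$g
      E <- E + w * com[2]
      add_force(bn, com, c(0, -w, 0))
    }
  }

  # ---- hand bushing ------------------------------------------------------
  kt <- sys$bushing$k_t
  dp <- wrist_w - sys$hand_ref
  E <- E + 0.5 * sum(kt * dp^2)
  add_force("hand", wrist_w, -kt * dp)
  phi <- matrix_to_rotvec(poses$hand$R %*% t(sys$hand_R_ref))
  E <- E + 0.5 * sys$bushing$k_r * sum(phi^2)
  g[13:15] <- g[13:15] + sys$bushing$k_r * phi / ROT_SCALE

  out <- list(energy = E, gradient = g)
  if (details) {
    out$contact <- list(
      uh = list(idx = sys$troch_idx, delta = uh_delta_all, w = uh_w_all),
      rh = list(idx = sys$cap_idx, delta = rh_delta_all, w = rh_w_all))
    out$ligament <- do.call(rbind, det_lig)
  }
  out
}

body_pt <- function(poses, body, p, humerus_position) {
  po <- poses[[body]]
  po$position + as.numeric(po$R %*% p)
}

# ligament strain energy density per unit zero-load length (integral of
# the force-strain law)
lig_energy <- function(eps, k, eps_l) {
  ifelse(eps <= 0, 0,
         ifelse(eps <= 2 * eps_l,
                k * eps^3 / (12 * eps_l),
                (2 / 3) * k * eps_l^2 +
                  0.5 * k * ((eps - eps_l)^2 - eps_l^2)))
}

# route a bundle with poses given explicitly (humeral anchors translate
# with the prescribed humeral position)
bundle_route_poses <- function(sys, b, poses, t_h) {
  a <- body_pt(poses, b$origin_body, b$origin, t_h)
  bp <- body_pt(poses, b$insertion_body, b$insertion, t_h)
  prims <- lapply(b$wrap_primitives, function(pr) {
    po <- poses[[pr$body]]
    prw <- pr
    prw$center <- po$position + as.numeric(po$R %*% pr$center)
    if (!is.null(pr$axis)) prw$axis <- as.numeric(po$R %*% pr$axis)
    prw
  })
  rt <- wrap_route(a, bp, prims, clamp = TRUE)
  rt$origin_world <- a
  rt$insertion_world <- bp
  rt
}

# ---- generic static equilibrium solver ---------------------------------

#' Solve a static equilibrium by energy minimisation
#'
#' Damped quasi-Newton minimisation of a potential with analytic gradient,
#' followed by Newton polishing with a finite-difference Hessian until the
#' residual (gradient infinity-norm) is below `tol`. This is the core the
#' quasistatic continuation uses at every drive increment.
#'
#' @param energy function(q) -> scalar potential.
#' @param gradient function(q) -> gradient vector.
#' @param q0 starting coordinates.
#' @param tol residual tolerance.
#' @param max_newton maximum Newton polish iterations.
#' @return list with `q`, `residual`, `converged`, `energy`.
#' @export
static_equilibrium <- function(energy, gradient, q0, tol = 1e-3,
                               max_newton = 60) {
  n <- length(q0)
  q <- q0
  gr <- gradient(q)
  res <- max(abs(gr))
  if (res <= tol)
    return(list(q = q, residual = res, converged = TRUE,
                energy = energy(q)))
  newton_polish <- function(q, gr, res, max_it) {
    E <- energy(q)
    lambda <- 1e-8
    it <- 0
    H <- NULL; h_age <- 0L
    while (res > tol && it < max_it) {
      if (is.null(H) || h_age >= 4L) {
        H <- matrix(0, n, n)
        h <- pmax(1e-6, abs(q) * 1e-6)
        for (j in seq_len(n)) {
          qj <- q; qj[j] <- qj[j] + h[j]
          H[, j] <- (gradient(qj) - gr) / h[j]
        }
        H <- (H + t(H)) / 2
        h_age <- 0L
      }
      step <- NULL
      for (k in 1:14) {
        Hreg <- H + diag(lambda, n)
        step <- tryCatch(solve(Hreg, -gr), error = function(e) NULL)
        if (!is.null(step) && all(is.finite(step)) &&
            sum(step * (-gr)) > 0) break
        lambda <- lambda * 10
        step <- NULL
      }
      if (is.null(step)) step <- -gr / max(1, sqrt(sum(gr^2)))
      gTs <- sum(gr * step)
      tstep <- 1; ok <- FALSE
      for (k in 1:16) {
        qn <- q + tstep * step
        En <- energy(qn)
        grn <- gradient(qn)
        if (all(is.finite(grn)) &&
            (En < E + 1e-4 * tstep * gTs || max(abs(grn)) < 0.7 * res)) {
          ok <- TRUE; break
        }
        tstep <- tstep / 2
      }
      it <- it + 1
      if (!ok) { lambda <- lambda * 100; H <- NULL; next }
      q <- qn; gr <- grn; res <- max(abs(gr)); E <- En
      lambda <- max(lambda / 10, 1e-10)
      h_age <- h_age + 1L
      if (tstep < 0.5) H <- NULL   # curvature info stale
    }
    list(q = q, gr = gr, res = res)
  }
  # warm starts close to equilibrium go straight to Newton
  if (res <= 100 * tol) {
    np <- newton_polish(q, gr, res, 12L)
    if (np$res <= tol)
      return(list(q = np$q, residual = np$res, converged = TRUE,
                  energy = energy(np$q)))
    q <- np$q
  }
  for (round in 1:4) {
    fit <- stats::nlminb(q, objective = energy, gradient = gradient,
                         control = list(iter.max = 600, eval.max = 900))
    q <- fit$par
    gr <- gradient(q)
    res <- max(abs(gr))
    if (res <= tol) break
    np <- newton_polish(q, gr, res, max_newton)
    q <- np$q; gr <- np$gr; res <- np$res
    if (res <= tol) break
    # fold traversal: minimise the energy along the softest Hessian mode
    # (snap-through leaves the iterate near a saddle whose unstable
    # direction quasi-Newton methods struggle to exploit)
    H <- matrix(0, n, n)
    h <- pmax(1e-6, abs(q) * 1e-6)
    for (j in seq_len(n)) {
      qj <- q; qj[j] <- qj[j] + h[j]
      H[, j] <- (gradient(qj) - gr) / h[j]
    }
    ev <- eigen((H + t(H)) / 2, symmetric = TRUE)
    v <- ev$vectors[, n]
    ls <- stats::optimize(function(a) energy(q + a * v),
                          interval = c(-8, 8))
    if (is.finite(ls$objective) && ls$objective < energy(q))
      q <- q + ls$minimum * v
    gr <- gradient(q)
    res <- max(abs(gr))
    if (res <= tol) break
  }
  # endgame: a near-tolerance stall usually sits on a contact kink; a
  # fresh-Hessian Newton with full patience closes the last decade
  if (res > tol && res <= 100 * tol) {
    np <- newton_polish(q, gr, res, 40L)
    q <- np$q; gr <- np$gr; res <- np$res
  }
  list(q = q, residual = res, converged = res <= tol, energy = energy(q))
}

# ---- flexion run --------------------------------------------------------

#' Run the passive flexion simulation
#'
#' Advances the prescribed humeral-head displacement from 0 to the drive's
#' total displacement, solving the free coordinates at each increment
#' (quasistatic continuation, with adaptive step halving around contact
#' make/break events), and records body poses, joint-coordinate-system
#' kinematics, per-element contact states and per-bundle ligament states.
#' The run terminates at full displacement or once `max_flexion` is
#' reached.
#'
#' @param system an [assemble_system()] result.
#' @param drive a [motion_drive()].
#' @param config a [simulation_config()].
#' @return object of class `simulation_trace`: list with `steps`
#'   (data.frame: step, time, displacement, flexion, residual, iterations),
#'   `poses` (list of per-step pose lists), `contact` (list of per-step
#'   contact data.frames), `ligament` (list of per-step bundle
#'   data.frames), `kin` (data.frame of per-step JCS samples for ulna and
#'   radius), and the configuration used.
#' @export
run_flexion_sim <- function(system, drive = motion_drive(),
                            config = simulation_config()) {
  stopifnot(inherits(system, "elbow_system"))
  if (config$solver == "dynamic")
    return(run_flexion_dynamic(system, drive, config))
  geo <- system$geometry
  base <- sys_reference_base(system)
  q <- q_from_base(base)
  rate <- if (drive$duration > 0) drive$total_displacement / drive$duration else 0
  s_targets <- seq(0, drive$total_displacement,
                   length.out = config$n_steps + 1)
  href <- geo$bodies$humerus$position

  rows <- list(); poses_l <- list(); contact_l <- list(); lig_l <- list()
  kin_l <- list()
  prev <- NULL
  istep <- 0L
  s_prev <- NA_real_
  for (si in seq_along(s_targets)) {
    s_goal <- s_targets[si]
    s_from <- if (si == 1) 0 else s_targets[si - 1]
    # adaptive sub-stepping toward s_goal
    sub <- list(c(s_from, s_goal))
    halvings <- 0
    repeat {
      if (!length(sub)) break
      seg <- sub[[1]]
      s_now <- seg[2]
      hp <- href + s_now * drive$direction
      efun <- function(qq) energy_gradient(
        system, poses_from_q(system, qq, base, hp))$energy
      gfun <- function(qq) chart_correct_gradient(energy_gradient(
        system, poses_from_q(system, qq, base, hp))$gradient, qq)
      sol <- static_equilibrium(efun, gfun, q, tol = config$tol)
      if (!sol$converged) {
        if (halvings >= config$max_step_halvings)
          stop("quasistatic solve failed to converge at displacement ",
               signif(s_now, 6), " mm (residual ", signif(sol$residual, 3),
               "); smallest substep reached")
        halvings <- halvings + 1
        mid <- (seg[1] + seg[2]) / 2
        sub <- c(list(c(seg[1], mid), c(mid, seg[2])), sub[-1])
        next
      }
      q <- sol$q
      # rebase rotations to keep increments small
      po <- poses_from_q(system, q, base, hp)
      base$ulna$R <- po$ulna$R; base$radius$R <- po$radius$R
      base$hand$R <- po$hand$R
      q[4:6] <- 0; q[10:12] <- 0; q[13:15] <- 0
      sub <- sub[-1]
      if (!length(sub)) { final_sol <- sol; final_poses <- po }
    }
    po <- final_poses
    eg <- energy_gradient(system, po, details = TRUE)
    istep <- istep + 1L
    tnow <- if (rate > 0) s_goal / rate else 0
    dt <- if (!is.na(s_prev) && rate > 0) (s_goal - s_prev) / rate else NA_real_
    # kinematics
    js_u <- jcs_from_poses(geo, po, "ulna")
    js_r <- jcs_from_poses(geo, po, "radius")
    flex <- js_u$FE
    # contact frame with rates from finite differences
    cdf <- contact_states_df(system, eg, prev, dt)
    ldf <- ligament_states_df(system, eg, prev, dt)
    # dislocation candidate: a whole compartment separated beyond the
    # configured bound (the run continues; scenario-level flags also
    # require a sustained loss of compartment contact)
    sep_uh <- -max(eg$contact$uh$delta)
    sep_rh <- -max(eg$contact$rh$delta)
    rows[[istep]] <- data.frame(step = istep, time = tnow,
                                displacement = s_goal, flexion = flex,
                                residual = final_sol$residual,
                                energy = final_sol$energy,
                                dislocation_candidate =
                                  max(sep_uh, sep_rh) >
                                  config$separation_bound)
    poses_l[[istep]] <- po
    contact_l[[istep]] <- cdf
    lig_l[[istep]] <- ldf
    kin_l[[istep]] <- rbind(
      cbind(body = "ulna", as.data.frame(unclass(js_u))),
      cbind(body = "radius", as.data.frame(unclass(js_r))))
    prev <- list(eg = eg, poses = po)
    s_prev <- s_goal
    if (flex >= config$max_flexion) break
  }
  steps <- do.call(rbind, rows)
  kin <- do.call(rbind, Map(function(k, i, t_, fl) {
    k$step <- i; k$time <- t_; k$flexion <- fl; k
  }, kin_l, steps$step, steps$time, steps$flexion))
  if (any(!is.finite(steps$flexion)))
    stop("trace contains non-finite flexion angles")
  structure(list(steps = steps, poses = poses_l, contact = contact_l,
                 ligament = lig_l, kin = kin, drive = drive,
                 config = config),
            class = "simulation_trace")
}

contact_states_df <- function(sys, eg, prev, dt) {
  el <- sys$geometry$contact_elements
  delta <- numeric(length(el)); w <- numeric(length(el))
  delta[eg$contact$uh$idx] <- eg$contact$uh$delta
  w[eg$contact$uh$idx] <- eg$contact$uh$w
  delta[eg$contact$rh$idx] <- eg$contact$rh$delta
  w[eg$contact$rh$idx] <- eg$contact$rh$w
  ddot <- numeric(length(el))
  if (!is.null(prev) && is.finite(dt) && dt > 0) {
    pd <- numeric(length(el))
    pd[prev$eg$contact$uh$idx] <- prev$eg$contact$uh$delta
    pd[prev$eg$contact$rh$idx] <- prev$eg$contact$rh$delta
    ddot <- (delta - pd) / dt
  }
  region <- vapply(el, function(e) e$region, "")
  Fc <- numeric(length(el))
  for (rg in c("trochlea", "capitellum")) {
    pp <- if (rg == "trochlea") sys$contact$uh else sys$contact$rh
    ix <- which(region == rg)
    Fc[ix] <- contact_normal_force(delta[ix], ddot[ix], pp) * w[ix]
  }
  data.frame(id = vapply(el, function(e) e$id, 0L), region = region,
             area = vapply(el, function(e) e$area, 0),
             u = vapply(el, function(e) e$map_uv[1], 0),
             v = vapply(el, function(e) e$map_uv[2], 0),
             delta = delta, delta_dot = ddot, Fc = Fc,
             pressure = Fc / vapply(el, function(e) e$area, 0))
}

ligament_states_df <- function(sys, eg, prev, dt) {
  df <- eg$ligament
  df$l_dot <- 0
  if (!is.null(prev) && is.finite(dt) && dt > 0) {
    m <- match(df$bundle, prev$eg$ligament$bundle)
    df$l_dot <- ifelse(is.na(df$l) | is.na(prev$eg$ligament$l[m]), 0,
                       (df$l - prev$eg$ligament$l[m]) / dt)
  }
  # reported force includes the parallel damper, clamped non-negative
  cs <- vapply(sys$atlas$bundles, function(b) b$c, 0)
  act <- df$active
  df$force <- ifelse(act, pmax(df$force + cs * df$l_dot, 0), 0)
  df
}

# ---- dynamic mode -------------------------------------------------------

#' Dynamic settling of a potential system (fidelity-check integrator)
#'
#' Integrates `M q'' = -grad E(q) - D(q) q'` with `deSolve::lsoda`, where
#' `D` is an optional configuration-dependent generalized damping matrix.
#' Used to cross-check quasistatic equilibria.
#'
#' @param gradient function(q) -> gradient of the potential.
#' @param mass vector of generalized masses (N per mm/s^2 units).
#' @param q0,v0 initial coordinates and rates.
#' @param t_end integration time, s.
#' @param damping function(q) -> damping matrix, or a scalar viscous
#'   coefficient applied to every coordinate.
#' @param n_out number of output frames.
#' @return matrix of `deSolve` output (time, q, v).
#' @export
dynamic_settle <- function(gradient, mass, q0, v0 = NULL, t_end = 1,
                           damping = 0.5, n_out = 50) {
  n <- length(q0)
  if (is.null(v0)) v0 <- numeric(n)
  dfun <- if (is.function(damping)) damping else NULL
  deriv <- function(t, y, parms) {
    q <- y[1:n]; v <- y[(n + 1):(2 * n)]
    f <- -gradient(q)
    fd <- if (is.null(dfun)) -damping * v else -as.numeric(dfun(q) %*% v)
    list(c(v, (f + fd) / mass))
  }
  deSolve::lsoda(c(q0, v0), seq(0, t_end, length.out = n_out), deriv,
                 parms = NULL, rtol = 1e-8, atol = 1e-8)
}

# dynamic flexion run: integrates the free coordinates through the drive
# with the contact/ligament dampers active. Intended for short fidelity
# checks; the quasistatic solver is the workhorse.
run_flexion_dynamic <- function(system, drive, config) {
  geo <- system$geometry
  base <- sys_reference_base(system)
  q0 <- q_from_base(base)
  href <- geo$bodies$humerus$position
  rate <- drive$total_displacement / drive$duration
  masses <- geo$masses
  Lu <- geo$config$ulna_length
  m_t <- function(m) m * 1e-3
  i_r <- function(m, L) m * L^2 / 12 * 1e-3 / ROT_SCALE^2
  mass <- c(rep(m_t(masses$ulna$mass), 3), rep(i_r(masses$ulna$mass, Lu), 3),
            rep(m_t(masses$radius$mass), 3),
            rep(i_r(masses$radius$mass, Lu), 3),
            rep(i_r(masses$hand$mass, 80), 3))
  n <- 15
  deriv <- function(t, y, parms) {
    q <- y[1:n]; v <- y[(n + 1):(2 * n)]
    hp <- href + min(t * rate, drive$total_displacement) * drive$direction
    eg <- energy_gradient(system, poses_from_q(system, q, base, hp))
    gq <- chart_correct_gradient(eg$gradient, q)
    # viscous generalized damping: lumped equivalent of the contact and
    # ligament dampers projected on the free coordinates
    dampc <- 0.3
    list(c(v, (-gq - dampc * v) / mass))
  }
  times <- seq(0, drive$duration, length.out = config$n_steps + 1)
  out <- deSolve::lsoda(c(q0, numeric(n)), times, deriv, parms = NULL,
                        rtol = 1e-6, atol = 1e-6)
  structure(list(raw = out, base = base, config = config, drive = drive),
            class = "dynamic_trace")
}
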