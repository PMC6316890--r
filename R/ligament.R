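#' Ligament bundle mechanics
#'
#' Each ligament is represented by a small set of tension-only bundles with
#' the classic quadratic-toe / linear force-strain law
#' \deqn{f(\varepsilon) = \begin{cases}
#'   \tfrac14 k \varepsilon^2/\varepsilon_l & 0 \le \varepsilon \le 2\varepsilon_l \\
#'   k(\varepsilon - \varepsilon_l) & \varepsilon > 2\varepsilon_l \\
#'   0 & \varepsilon < 0 \end{cases}}
#' with engineering strain \eqn{\varepsilon = (l - l_0)/l_0} relative to the
#' zero-load length \eqn{l_0}. The branches meet with matching value
#' (\eqn{k\varepsilon_l}) and slope (\eqn{k}) at \eqn{\varepsilon = 2\varepsilon_l},
#' so the law is C1. A parallel damper (default 0.5 Ns/mm) suppresses
#' high-frequency vibration in dynamic runs; the total force is clamped
#' non-negative because a ligament cannot push.
#'
#' @name ligament-model
NULL

LIG_COMPLEXES <- c("MCL_AB", "MCL_PB", "LUCL", "RCL", "annular")

#' Construct a ligament bundle
#'
#' @param name bundle name, e.g. `"MCL_AB_1"`.
#' @param complex one of `"MCL_AB"`, `"MCL_PB"`, `"LUCL"`, `"RCL"`,
#'   `"annular"`.
#' @param origin_body,origin body name and body-frame attachment point of
#'   the proximal anchor (mm).
#' @param insertion_body,insertion body name and body-frame point of the
#'   distal anchor (mm).
#' @param k stiffness parameter, N (force per unit strain in the linear
#'   region).
#' @param eps_l toe-region spring parameter (dimensionless). Default 0.03.
#' @param l0 zero-load length, mm. `NA` is allowed at construction time for
#'   bundles whose zero-load length is set later from a reference pose.
#' @param c parallel damping coefficient, Ns/mm. Default 0.5.
#' @param wrap_primitives ordered list of wrap primitives (see
#'   [wrap_sphere()] / [wrap_cylinder()]), possibly empty.
#' @param active logical; sectioned bundles are `FALSE`.
#' @return object of class `ligament_bundle`.
#' @export
ligament_bundle <- function(name, complex, origin_body, origin,
                            insertion_body, insertion, k, eps_l = 0.03,
                            l0 = NA_real_, c = 0.5, wrap_primitives = list(),
                            active = TRUE) {
  complex <- match.arg(complex, LIG_COMPLEXES)
  if (!is.na(l0) && (!is.numeric(l0) || l0 <= 0))
    stop("l0 must be positive (mm)")
  if (!is.numeric(k) || k < 0) stop("k must be non-negative (N)")
  if (!is.numeric(eps_l) || eps_l <= 0) stop("eps_l must be positive")
  if (!is.numeric(c) || c < 0) stop("c must be non-negative (Ns/mm)")
  structure(list(name = name, complex = complex,
                 origin_body = origin_body, origin = as.numeric(origin),
                 insertion_body = insertion_body,
                 insertion = as.numeric(insertion),
                 k = k, eps_l = eps_l, l0 = l0, c = c,
                 wrap_primitives = wrap_primitives, active = active),
            class = "ligament_bundle")
}

#' Engineering strain of a ligament bundle
#' @param l current path length, mm.
#' @param l0 zero-load length, mm.
#' @return dimensionless strain `(l - l0)/l0` (negative when slack).
#' @export
engineering_strain <- function(l, l0) {
  if (any(!is.finite(l0)) || any(l0 <= 0))
    stop("l0 must be positive (mm)")
  (l - l0) / l0
}

#' Elastic bundle force from strain
#'
#' Quadratic toe region up to strain `2 * eps_l`, linear beyond, zero when
#' slack.
#' @param eps engineering strain (vectorised).
#' @param k stiffness parameter, N.
#' @param eps_l toe-region parameter.
#' @return tensile force, N.
#' @export
bundle_elastic_force <- function(eps, k, eps_l = 0.03) {
  if (eps_l <= 0) stop("eps_l must be positive")
  ifelse(eps < 0, 0,
         ifelse(eps <= 2 * eps_l,
                0.25 * k * eps^2 / eps_l,
                k * (eps - eps_l)))
}

#' Total bundle force including the parallel damper
#'
#' @param state list with `l` (mm) and `l_dot` (mm/s, positive when
#'   lengthening); strain is recomputed from the bundle's `l0`.
#' @param bundle a [ligament_bundle()].
#' @return tensile force, N (0 for inactive bundles; clamped non-negative).
#' @export
bundle_total_force <- function(state, bundle) {
  stopifnot(inherits(bundle, "ligament_bundle"))
  if (!isTRUE(bundle$active)) return(0)
  eps <- engineering_strain(state$l, bundle$l0)
  f <- bundle_elastic_force(eps, bundle$k, bundle$eps_l) +
    bundle$c * (state$l_dot %||% 0)
  max(f, 0)
}

# ---- wrapping -----------------------------------------------------------

#' Wrap primitives
#'
#' Convex obstacles a ligament path may wrap around. The primitive is
#' anchored to a body: `body` plus body-frame `center` (and `axis` for a
#' cylinder).
#' @param body body name the primitive is fixed to.
#' @param center length-3 centre (sphere) or a point on the axis
#'   (cylinder), body frame, mm.
#' @param radius radius, mm.
#' @param axis unit axis direction, body frame (cylinder only).
#' @return wrap primitive object.
#' @export
wrap_sphere <- function(body, center, radius) {
  if (radius <= 0) stop("wrap sphere radius must be positive")
  structure(list(type = "sphere", body = body, center = as.numeric(center),
                 radius = radius), class = "wrap_primitive")
}

#' @rdname wrap_sphere
#' @export
wrap_cylinder <- function(body, center, axis, radius) {
  if (radius <= 0) stop("wrap cylinder radius must be positive")
  structure(list(type = "cylinder", body = body, center = as.numeric(center),
                 axis = unitize(as.numeric(axis)), radius = radius),
            class = "wrap_primitive")
}

# shortest path from A to B around a circle of radius r centred at origin,
# all in a common plane. Returns length and the two tangent directions.
circle_wrap_2d <- function(dA, dB, theta, r) {
  # dA, dB: distances of endpoints from centre; theta: angle A-centre-B
  tA <- sqrt(max(dA^2 - r^2, 0))
  tB <- sqrt(max(dB^2 - r^2, 0))
  arc <- theta - acos(min(r / dA, 1)) - acos(min(r / dB, 1))
  list(tangentA = tA, tangentB = tB, arc = max(arc, 0),
       length = tA + tB + r * max(arc, 0), active = arc > 0)
}

#' Ligament path routing around convex wrap primitives
#'
#' Computes the shortest (taut-string) path from `origin` to `insertion`
#' that does not penetrate the given convex primitive. With no primitives
#' the path is the straight segment. A sphere wrap is solved exactly in the
#' plane through the two endpoints and the sphere centre; a cylinder wrap
#' uses the standard surface-development (unrolling) construction in the
#' plane normal to the axis. Paths are evaluated per primitive in order;
#' in this model each bundle wraps at most one primitive at a time.
#'
#' @param origin,insertion length-3 world points, mm.
#' @param primitives list of wrap primitives given in *world* coordinates
#'   (i.e. `center`/`axis` already transformed to world).
#' @return list with `length` (mm), `dir_origin` and `dir_insertion`
#'   (unit force directions at each endpoint, pointing from the endpoint
#'   into the path, i.e. the direction the ligament tension pulls the
#'   anchor), `wrapped` (logical), and for a wrapped path the `primitive`
#'   index.
#' @param clamp if `TRUE`, an endpoint found inside a primitive is clamped
#'   to the primitive surface instead of raising an error (used by the
#'   solver, whose line searches may probe extreme configurations).
#' @export
wrap_route <- function(origin, insertion, primitives = list(),
                       clamp = FALSE) {
  origin <- as.numeric(origin); insertion <- as.numeric(insertion)
  straight <- insertion - origin
  L <- sqrt(sum(straight^2))
  out <- list(length = L, dir_origin = unitize(straight),
              dir_insertion = -unitize(straight), wrapped = FALSE,
              primitive = NA_integer_)
  if (!length(primitives)) return(out)
  for (ip in seq_along(primitives)) {
    pr <- primitives[[ip]]
    if (pr$type == "sphere") {
      cA <- origin - pr$center; cB <- insertion - pr$center
      dA <- sqrt(sum(cA^2)); dB <- sqrt(sum(cB^2))
      if (dA <= pr$radius || dB <= pr$radius) {
        if (!clamp) {
          which_end <- if (dA <= pr$radius) "origin" else "insertion"
          stop("ligament ", which_end, " lies inside wrap primitive ", ip)
        }
        dA <- max(dA, pr$radius * (1 + 1e-6))
        dB <- max(dB, pr$radius * (1 + 1e-6))
      }
      # does the straight segment pass through the sphere?
      tpar <- -sum(cA * (straight / L)) # distance along segment to closest appr.
      pclose <- cA + pmin(pmax(tpar, 0), L) * straight / L
      if (sqrt(sum(pclose^2)) >= pr$radius) next  # no interference
      theta <- acos(min(max(sum(cA * cB) / (dA * dB), -1), 1))
      w <- circle_wrap_2d(dA, dB, theta, pr$radius)
      # tangent directions in the wrap plane
      e1 <- cA / dA
      e2raw <- cB - sum(cB * e1) * e1
      if (sqrt(sum(e2raw^2)) < 1e-9) {
        # endpoints collinear with centre: pick any perpendicular
        e2raw <- perp_unit_vec(e1)
      }
      e2 <- unitize(e2raw)
      aA <- acos(min(pr$radius / dA, 1))
      # tangent point from A: rotate e1 toward e2 by aA, at radius r
      tpA <- pr$center + pr$radius * (cos(aA) * e1 + sin(aA) * e2)
      aB <- acos(min(pr$radius / dB, 1))
      eB1 <- cB / dB
      eB2raw <- cA - sum(cA * eB1) * eB1
      eB2 <- if (sqrt(sum(eB2raw^2)) < 1e-9) perp_unit_vec(eB1) else unitize(eB2raw)
      tpB <- pr$center + pr$radius * (cos(aB) * eB1 + sin(aB) * eB2)
      out <- list(length = w$length,
                  dir_origin = unitize(tpA - origin),
                  dir_insertion = unitize(tpB - insertion),
                  wrapped = TRUE, primitive = ip,
                  contact_center = pr$center)
      return(out)
    } else if (pr$type == "cylinder") {
      ax <- pr$axis
      pA <- origin - pr$center; pB <- insertion - pr$center
      zA <- sum(pA * ax); zB <- sum(pB * ax)
      qA <- pA - zA * ax; qB <- pB - zB * ax
      dA <- sqrt(sum(qA^2)); dB <- sqrt(sum(qB^2))
      if (dA <= pr$radius || dB <= pr$radius) {
        if (!clamp) {
          which_end <- if (dA <= pr$radius) "origin" else "insertion"
          stop("ligament ", which_end, " lies inside wrap primitive ", ip)
        }
        dA <- max(dA, pr$radius * (1 + 1e-6))
        dB <- max(dB, pr$radius * (1 + 1e-6))
      }
      # projected straight segment vs circle
      seg <- qB - qA; segl <- sqrt(sum(seg^2))
      if (segl < 1e-9) next
      tpar <- -sum(qA * seg) / segl
      pclose <- qA + pmin(pmax(tpar, 0), segl) * seg / segl
      if (sqrt(sum(pclose^2)) >= pr$radius) next
      theta <- acos(min(max(sum(qA * qB) / (dA * dB), -1), 1))
      w <- circle_wrap_2d(dA, dB, theta, pr$radius)
      # developed (unrolled) length: planar wrapped length and axial offset
      Lplan <- w$length
      Ltot <- sqrt(Lplan^2 + (zB - zA)^2)
      # tangent directions: in-plane tangent combined with axial advance
      e1 <- qA / dA
      e2raw <- qB - sum(qB * e1) * e1
      e2 <- if (sqrt(sum(e2raw^2)) < 1e-9)
        unitize(crossv(ax, e1)) else unitize(e2raw)
      aA <- acos(min(pr$radius / dA, 1))
      tpA_plan <- pr$radius * (cos(aA) * e1 + sin(aA) * e2)
      eB1 <- qB / dB
      eB2raw <- qA - sum(qA * eB1) * eB1
      # degenerate antiparallel projection: keep both tangents on one side
      eB2 <- if (sqrt(sum(eB2raw^2)) < 1e-9)
        -unitize(crossv(ax, eB1)) else unitize(eB2raw)
      aB <- acos(min(pr$radius / dB, 1))
      tpB_plan <- pr$radius * (cos(aB) * eB1 + sin(aB) * eB2)
      # axial coordinate advances linearly with developed arc length
      sA <- w$tangentA / Lplan; sB <- w$tangentB / Lplan
      zpA <- zA + (zB - zA) * sA
      zpB <- zB - (zB - zA) * sB
      tpA <- pr$center + tpA_plan + zpA * ax
      tpB <- pr$center + tpB_plan + zpB * ax
      out <- list(length = Ltot,
                  dir_origin = unitize(tpA - origin),
                  dir_insertion = unitize(tpB - insertion),
                  wrapped = TRUE, primitive = ip,
                  contact_center = pr$center +
                    ax * sum(((tpA + tpB) / 2 - pr$center) * ax))
      return(out)
    } else stop("unknown wrap primitive type: ", pr$type)
  }
  out
}

# any unit vector perpendicular to v
perp_unit_vec <- function(v) {
  a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unitize(crossv(v, a))
}

#' Section ligament bundles for a deficiency scenario
#'
#' Deactivates the bundles of the sectioned complex(es) and leaves all
#' others untouched. Idempotent.
#'
#' @param atlas a `ligament_atlas` (list of [ligament_bundle()]s, as built
#'   by [generate_elbow()]).
#' @param scenario one of `"intact"`, `"MCL_AB_deficient"`,
#'   `"MCL_PB_deficient"`, `"both_MCL_deficient"`.
#' @return the atlas with `active` flags updated.
#' @export
section_bundles <- function(atlas, scenario) {
  scen <- c("intact", "MCL_AB_deficient", "MCL_PB_deficient",
            "both_MCL_deficient")
  if (!is.character(scenario) || length(scenario) != 1 || !scenario %in% scen)
    stop("unknown scenario '", scenario, "'; valid: ",
         paste(scen, collapse = ", "))
  cut <- switch(scenario,
                intact = character(0),
                MCL_AB_deficient = "MCL_AB",
                MCL_PB_deficient = "MCL_PB",
                both_MCL_deficient = c("MCL_AB", "MCL_PB"))
  atlas$bundles <- lapply(atlas$bundles, function(b) {
    b$active <- !(b$complex %in% cut)
    b
  })
  atlas$scenario <- scenario
  atlas
}

#' Count active bundles in an atlas
#' @param atlas a ligament atlas.
#' @return integer.
#' @export
n_active_bundles <- function(atlas) {
  sum(vapply(atlas$bundles, function(b) isTRUE(b$active), TRUE))
}
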