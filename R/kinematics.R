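#' Joint-coordinate-system kinematics
#'
#' Clinical six-degree-of-freedom decomposition of the ulna (or radius)
#' pose relative to the humerus on a Grood-Suntay axis set: a body-fixed
#' flexion axis on the humerus (trans-epicondylar), a body-fixed long axis
#' on the distal bone, and a floating axis completing the triad. Angles
#' factor the relative anatomical rotation as
#' `Rz(flexion) Rx(-valgus) Ry(internal)`; translations are the
#' projections of the inter-origin vector onto the three JCS axes.
#'
#' Sign conventions (right arm): flexion-extension FE positive in flexion;
#' varus-valgus VV positive in valgus; internal-external IE positive in
#' internal rotation; medial-lateral ML positive medially;
#' anterior-posterior AP positive anteriorly; superior-inferior SI
#' positive superiorly.
#'
#' @name jcs-kinematics
NULL

#' Anatomical body frame
#'
#' @param body body name.
#' @param origin world origin, mm.
#' @param axes 3x3 matrix whose columns are the orthonormal x (anterior),
#'   y (long, proximal) and z (flexion / lateral) axes in world
#'   coordinates.
#' @return object of class `body_frame`.
#' @export
body_frame <- function(body, origin, axes) {
  axes <- as.matrix(axes)
  if (max(abs(t(axes) %*% axes - diag(3))) > 1e-6)
    stop("body frame axes must be orthonormal")
  if (det(axes) < 0) stop("body frame axes must be right-handed")
  structure(list(body = body, origin = as.numeric(origin), axes = axes),
            class = "body_frame")
}

# orthonormal right-handed frame from a long axis and an approximate
# lateral direction
frame_from_axes <- function(body, origin, y_long, z_approx) {
  y <- unitize(y_long)
  x <- unitize(crossv(y, z_approx))
  z <- crossv(x, y)
  body_frame(body, origin, cbind(x, y, z))
}

#' Build an anatomical frame from landmarks at given poses
#'
#' @param geo an `elbow_geometry`.
#' @param body `"humerus"`, `"ulna"` or `"radius"`.
#' @param poses named list of body poses; `NULL` uses the reference pose.
#' @return a [body_frame()].
#' @export
build_body_frame <- function(geo, body, poses = NULL) {
  lw <- function(bn, nm) body_point_world(geo, bn, geo$landmarks[[bn]][[nm]],
                                          poses = poses)
  if (body == "humerus") {
    org <- lw("humerus", "trochlea_center")
    z0 <- unitize(lw("humerus", "lateral_epicondyle") -
                    lw("humerus", "medial_epicondyle"))
    ylong <- lw("humerus", "humeral_head") - org
    y <- unitize(ylong)
    x <- unitize(crossv(y, z0))
    z <- crossv(x, y)
    return(body_frame(body, org, cbind(x, y, z)))
  }
  if (body == "ulna") {
    org <- lw("ulna", "notch_center")
    ylong <- org - lw("ulna", "ulna_styloid")
    zapp <- lw("ulna", "radial_notch") - org
    return(frame_from_axes(body, org, ylong, zapp))
  }
  if (body == "radius") {
    org <- lw("radius", "radial_head_center")
    ylong <- org - lw("radius", "radial_styloid")
    zapp <- lw("radius", "radial_head_lateral") - org
    return(frame_from_axes(body, org, ylong, zapp))
  }
  stop("no anatomical frame defined for body '", body, "'")
}

#' Decompose a relative pose into JCS angles and translations
#'
#' @param frame_humerus humeral [body_frame()].
#' @param frame_distal distal-bone [body_frame()] (ulna or radius).
#' @return list of class `jcs_sample`: `FE`, `VV`, `IE` (degrees), `ML`,
#'   `AP`, `SI` (mm). A warning is raised near the gimbal configuration
#'   (|VV| approaching 90 degrees); values are still returned.
#' @export
decompose_jcs <- function(frame_humerus, frame_distal) {
  Ah <- frame_humerus$axes; Ad <- frame_distal$axes
  Q <- t(Ah) %*% Ad
  sb <- min(max(Q[3, 2], -1), 1)
  b <- asin(sb)
  if (abs(cos(b)) < 1e-4)
    warning("JCS decomposition near gimbal lock (|varus-valgus| ~ 90 deg)")
  a <- atan2(-Q[1, 2], Q[2, 2])
  cc <- atan2(-Q[3, 1], Q[3, 3])
  qv <- frame_distal$origin - frame_humerus$origin
  e1 <- Ah[, 3]
  e3 <- Ad[, 2]
  e2 <- unitize(crossv(e3, e1))
  structure(list(FE = rad2deg(a), VV = rad2deg(-b), IE = rad2deg(cc),
                 ML = -sum(qv * e1), AP = sum(qv * e2), SI = sum(qv * e3)),
            class = "jcs_sample")
}

#' Compose a distal frame back from a JCS sample
#'
#' Exact inverse of [decompose_jcs()] given the humeral frame: rebuilds
#' the distal anatomical frame (axes and origin).
#'
#' @param sample a `jcs_sample` (or plain list with the six fields).
#' @param frame_humerus humeral [body_frame()].
#' @param distal_body body name for the returned frame.
#' @return a [body_frame()].
#' @export
compose_jcs <- function(sample, frame_humerus, distal_body = "ulna") {
  a <- deg2rad(sample$FE); b <- -deg2rad(sample$VV); cc <- deg2rad(sample$IE)
  Q <- rot_z(a) %*% rot_x(b) %*% rot_y(cc)
  Ah <- frame_humerus$axes
  Ad <- Ah %*% Q
  e1 <- Ah[, 3]; e3 <- Ad[, 2]; e2 <- unitize(crossv(e3, e1))
  B <- cbind(e1, e2, e3)
  comp <- c(-sample$ML, sample$AP, sample$SI)
  qv <- solve(t(B), comp)
  body_frame(distal_body, frame_humerus$origin + qv, Ad)
}

# JCS of a body relative to the humerus at given poses
jcs_from_poses <- function(geo, poses, body) {
  fh <- build_body_frame(geo, "humerus", poses)
  fd <- build_body_frame(geo, body, poses)
  decompose_jcs(fh, fd)
}

#' Resample a trace on a regular flexion grid
#'
#' Linear interpolation of each JCS degree of freedom at flexion grid
#' points over the half-open grid `[start, stop)` with the given spacing
#' (so 50 to 130 degrees at 2 degrees yields exactly 40 samples).
#' Interpolation uses the monotone non-decreasing envelope of the flexion
#' history (contact make/break can produce tiny local reversals).
#'
#' @param trace a `simulation_trace` from [run_flexion_sim()].
#' @param start,stop,step flexion grid, degrees.
#' @param body `"ulna"` or `"radius"`.
#' @return data.frame with `flexion` plus the six JCS DOFs.
#' @export
resample_by_flexion <- function(trace, start = 50, stop = 130, step = 2,
                                body = "ulna") {
  kin <- trace$kin[trace$kin$body == body, , drop = FALSE]
  x <- kin$flexion
  keep <- x >= cummax(x) - 1e-12
  kin <- kin[keep, , drop = FALSE]
  x <- kin$flexion
  if (min(x) > start || max(x) < stop - 1e-9)
    stop("trace flexion range [", signif(min(x), 4), ", ",
         signif(max(x), 4), "] deg does not cover the requested grid [",
         start, ", ", stop, "]")
  grid <- seq(start, stop - step, by = step)
  out <- data.frame(flexion = grid)
  for (dof in c("FE", "VV", "IE", "ML", "AP", "SI"))
    out[[dof]] <- stats::approx(x, kin[[dof]], xout = grid, ties = mean)$y
  out$body <- body
  out
}

#' Per-DOF differences of a deficient condition against the intact elbow
#'
#' Elementwise condition-minus-intact differences on the shared flexion
#' grid, with the summary mean and sample standard deviation over the
#' grid for each degree of freedom.
#'
#' @param samples_condition,samples_intact data.frames from
#'   [resample_by_flexion()] on the same grid.
#' @return list with `diff` (data.frame of per-grid-point differences) and
#'   `summary` (data.frame: dof, mean, sd).
#' @export
difference_vs_intact <- function(samples_condition, samples_intact) {
  if (nrow(samples_condition) != nrow(samples_intact) ||
      max(abs(samples_condition$flexion - samples_intact$flexion)) > 1e-9)
    stop("flexion grid mismatch between condition and intact samples")
  dofs <- c("IE", "VV", "SI", "AP", "ML")
  d <- data.frame(flexion = samples_condition$flexion)
  for (dof in dofs)
    d[[dof]] <- samples_condition[[dof]] - samples_intact[[dof]]
  summ <- data.frame(
    dof = dofs,
    mean = vapply(dofs, function(k) mean(d[[k]]), 0),
    sd = vapply(dofs, function(k) stats::sd(d[[k]]), 0),
    row.names = NULL)
  list(diff = d, summary = summ)
}
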