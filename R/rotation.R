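#' Rotation and pose utilities
#'
#' Small self-contained SO(3) toolkit used throughout the simulator: rotation
#' vectors (axis-angle), rotation matrices and unit quaternions, plus the
#' skew-symmetric cross-product matrix. All angles are in radians unless a
#' function name says otherwise.
#'
#' @name rotation-utils
#' @keywords internal
NULL

#' Cross-product (skew-symmetric) matrix
#' @param v numeric length-3 vector.
#' @return 3x3 matrix `S` with `S %*% w == v x w`.
#' @keywords internal
skew3 <- function(v) {
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), 3, 3)
}

#' Rotation matrix from a rotation vector (exponential map)
#' @param phi numeric length-3 rotation vector (axis * angle, radians).
#' @return 3x3 rotation matrix.
#' @export
rotvec_to_matrix <- function(phi) {
  stopifnot(length(phi) == 3, all(is.finite(phi)))
  th <- sqrt(sum(phi^2))
  if (th < 1e-12) {
    K <- skew3(phi)
    return(diag(3) + K + 0.5 * K %*% K)
  }
  K <- skew3(phi / th)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

#' Rotation vector from a rotation matrix (logarithm map)
#' @param R 3x3 rotation matrix.
#' @return numeric length-3 rotation vector with angle in `[0, pi]`.
#' @export
matrix_to_rotvec <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- max(-1, min(1, ct))
  th <- acos(ct)
  if (th < 1e-9) {
    return(c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2)
  }
  if (th > pi - 1e-6) {
    # near pi: extract axis from the symmetric part
    B <- (R + diag(3)) / 2
    ax <- sqrt(pmax(diag(B), 0))
    # fix signs using off-diagonals
    i <- which.max(ax)
    if (i == 1) {
      ax[2] <- B[1, 2] / max(ax[1], 1e-12) ; ax[3] <- B[1, 3] / max(ax[1], 1e-12)
    } else if (i == 2) {
      ax[1] <- B[1, 2] / max(ax[2], 1e-12) ; ax[3] <- B[2, 3] / max(ax[2], 1e-12)
    } else {
      ax[1] <- B[1, 3] / max(ax[3], 1e-12) ; ax[2] <- B[2, 3] / max(ax[3], 1e-12)
    }
    ax <- ax / sqrt(sum(ax^2))
    return(ax * th)
  }
  c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / (2 * sin(th)) * th
}

#' Unit quaternion (w, x, y, z) from a rotation matrix
#' @param R 3x3 rotation matrix.
#' @return numeric length-4 unit quaternion, scalar part first, `w >= 0`.
#' @export
matrix_to_quat <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(diag(R))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
             (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
             0.25 * s, (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  if (q[1] < 0) q <- -q
  q / sqrt(sum(q^2))
}

#' Rotation matrix from a unit quaternion (w, x, y, z)
#' @param q numeric length-4 quaternion; normalised internally.
#' @return 3x3 rotation matrix.
#' @export
quat_to_matrix <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

#' Elementary rotation matrices
#' @param a angle in radians.
#' @return 3x3 rotation matrix about the named axis.
#' @keywords internal
rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
#' @rdname rot_x
#' @keywords internal
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
#' @rdname rot_x
#' @keywords internal
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)

#' Normalise a vector to unit length
#' @param v numeric vector.
#' @keywords internal
unitize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-300) stop("cannot normalise a zero vector")
  v / n
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded geometry generation is a
#' pure function of its arguments and does not disturb the caller's RNG
#' stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
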