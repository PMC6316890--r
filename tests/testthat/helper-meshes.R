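# programmatic fixtures shared across test files

# flat rectangular patch in the xy-plane, triangulated on a fine grid,
# outward normal +z
flat_patch_mesh <- function(lx = 20, ly = 20, nx = 20, ny = 20) {
  xs <- seq(0, lx, length.out = nx + 1)
  ys <- seq(0, ly, length.out = ny + 1)
  P <- array(0, c(nx + 1, ny + 1, 3))
  for (i in seq_len(nx + 1)) for (j in seq_len(ny + 1))
    P[i, j, ] <- c(xs[i], ys[j], 0)
  V <- matrix(P, (nx + 1) * (ny + 1), 3)
  idx <- function(i, j) (j - 1) * (nx + 1) + i
  faces <- list()
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    faces[[length(faces) + 1]] <- c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1))
    faces[[length(faces) + 1]] <- c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
  }
  tri_surface(V, do.call(rbind, faces), open = TRUE)
}

# cylinder sector surface of radius r, length L, angular extent ang,
# outward normals away from the axis (z axis = cylinder axis)
cylinder_sector_mesh <- function(r = 15, L = 30, ang = pi, na = 40, nz = 20) {
  th <- seq(0, ang, length.out = na + 1)
  zs <- seq(0, L, length.out = nz + 1)
  V <- matrix(0, (na + 1) * (nz + 1), 3)
  k <- 0
  for (j in seq_len(nz + 1)) for (i in seq_len(na + 1)) {
    k <- k + 1
    V[k, ] <- c(r * cos(th[i]), r * sin(th[i]), zs[j])
  }
  idx <- function(i, j) (j - 1) * (na + 1) + i
  faces <- list()
  for (j in seq_len(nz)) for (i in seq_len(na)) {
    faces[[length(faces) + 1]] <- c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1))
    faces[[length(faces) + 1]] <- c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
  }
  tri_surface(V, do.call(rbind, faces), open = TRUE)
}

# unit-ish sphere mesh (watertight enough for signed distance tests)
sphere_mesh <- function(center = c(0, 0, 0), radius = 1, n = 40) {
  th <- seq(1e-3, pi - 1e-3, length.out = n)
  ph <- seq(0, 2 * pi - 2 * pi / (2 * n), length.out = 2 * n)
  V <- matrix(0, n * 2 * n, 3)
  k <- 0
  for (i in seq_len(n)) for (j in seq_len(2 * n)) {
    k <- k + 1
    V[k, ] <- center + radius * c(sin(th[i]) * cos(ph[j]),
                                  cos(th[i]),
                                  sin(th[i]) * sin(ph[j]))
  }
  idx <- function(i, j) (i - 1) * (2 * n) + ((j - 1) %% (2 * n)) + 1
  faces <- list()
  for (i in seq_len(n - 1)) for (j in seq_len(2 * n)) {
    faces[[length(faces) + 1]] <- c(idx(i, j), idx(i, j + 1), idx(i + 1, j + 1))
    faces[[length(faces) + 1]] <- c(idx(i, j), idx(i + 1, j + 1), idx(i + 1, j))
  }
  tri_surface(V, do.call(rbind, faces), open = TRUE)
}

# random rotation matrix from a uniformly random unit quaternion
random_rotation <- function() {
  q <- stats::rnorm(4)
  quat_to_matrix(q / sqrt(sum(q^2)))
}

# small geometry used by several suites (cached per session)
small_geo <- local({
  geo <- NULL
  function() {
    if (is.null(geo)) geo <<- generate_elbow(geometry_config(seed = 1))
    geo
  }
})
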