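#' Triangle-mesh file I/O
#'
#' Minimal readers and writers for the two exchange formats the package
#' uses: STL (ASCII and binary) and Wavefront OBJ. Meshes are represented
#' as [tri_surface()] objects. Writers emit millimetre coordinates
#' unchanged; readers do no unit conversion.
#'
#' @name mesh-io
NULL

#' Write a surface as ASCII or binary STL
#'
#' @param surface a [tri_surface()].
#' @param path output file path.
#' @param binary write binary STL (`TRUE`, default) or ASCII.
#' @param name solid name for ASCII output.
#' @return `path`, invisibly.
#' @export
write_stl <- function(surface, path, binary = TRUE, name = "elbowmbs") {
  stopifnot(inherits(surface, "tri_surface"))
  V <- surface$vertices; Fc <- surface$faces; N <- surface$face_normals
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw(sprintf("%-80s", paste("elbowmbs binary STL", name)))
    writeBin(hdr[1:80], con)
    writeBin(as.integer(nrow(Fc)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(Fc))) {
      writeBin(as.numeric(c(N[i, ], V[Fc[i, 1], ], V[Fc[i, 2], ], V[Fc[i, 3], ])),
               con, size = 4, endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("solid %s", name), con)
    for (i in seq_len(nrow(Fc))) {
      writeLines(c(
        sprintf("  facet normal %.9g %.9g %.9g", N[i, 1], N[i, 2], N[i, 3]),
        "    outer loop",
        sprintf("      vertex %.9g %.9g %.9g",
                V[Fc[i, 1:3], 1], V[Fc[i, 1:3], 2], V[Fc[i, 1:3], 3]),
        "    endloop",
        "  endfacet"), con)
    }
    writeLines(sprintf("endsolid %s", name), con)
  }
  invisible(path)
}

#' Read an STL file (ASCII or binary, auto-detected)
#'
#' Duplicate vertices are merged exactly (STL stores per-facet vertex
#' soup), so a watertight solid reads back with shared vertices.
#'
#' @param path STL file path.
#' @param open mark the surface as an open patch.
#' @return a [tri_surface()].
#' @export
read_stl <- function(path, open = FALSE) {
  raw <- readBin(path, "raw", n = 512)
  is_ascii <- length(raw) >= 5 && identical(rawToChar(raw[1:5]), "solid") &&
    !any(raw == as.raw(0))
  if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    nums <- lapply(strsplit(trimws(vl), "\\s+"), function(x) as.numeric(x[2:4]))
    V <- do.call(rbind, nums)
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = 80)
    ntri <- readBin(con, "integer", size = 4, endian = "little")
    V <- matrix(0, ntri * 3, 3)
    for (i in seq_len(ntri)) {
      rec <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
      readBin(con, "raw", n = 2)
      V[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
    }
  }
  if (is.null(V) || nrow(V) < 3 || nrow(V) %% 3 != 0)
    stop("malformed STL file: ", path)
  key <- apply(round(V, 9), 1, paste, collapse = ",")
  uk <- !duplicated(key)
  idx <- match(key, key[uk])
  Vu <- V[uk, , drop = FALSE]
  Fc <- matrix(idx, ncol = 3, byrow = TRUE)
  tri_surface(Vu, Fc, open = open)
}

#' Write a surface as Wavefront OBJ
#' @inheritParams write_stl
#' @export
write_obj <- function(surface, path, name = "elbowmbs") {
  stopifnot(inherits(surface, "tri_surface"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("o %s", name), con)
  V <- surface$vertices; Fc <- surface$faces
  writeLines(sprintf("v %.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]), con)
  writeLines(sprintf("f %d %d %d", Fc[, 1], Fc[, 2], Fc[, 3]), con)
  invisible(path)
}

#' Read a Wavefront OBJ file (triangles only)
#' @inheritParams read_stl
#' @export
read_obj <- function(path, open = FALSE) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (!length(vl) || !length(fl)) stop("malformed OBJ file: ", path)
  V <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                             function(x) as.numeric(x[2:4])))
  faces <- lapply(strsplit(trimws(fl), "\\s+"), function(x) {
    ix <- as.integer(sub("/.*", "", x[-1]))
    if (length(ix) != 3) stop("read_obj supports triangle faces only")
    ix
  })
  tri_surface(V, do.call(rbind, faces), open = open)
}
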