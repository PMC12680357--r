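#' Read and write STL surface files
#'
#' Supports both binary and ASCII STL. STL stores an unindexed triangle
#' soup; on read, coincident vertices are merged at a declared tolerance
#' (default 1e-6 mm) so the pipeline sees shared-vertex topology. A
#' write-then-read roundtrip preserves coordinates to 32-bit float precision
#' and face topology.
#'
#' @param path file path.
#' @param merge_tolerance vertex-merge tolerance in mm.
#' @return `read_stl()`: a `sac_mesh`. `write_stl()`: the path, invisibly.
#' @export
read_stl <- function(path, merge_tolerance = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sz <- file.size(path)
  if (sz < 15) stop("malformed STL (file too short, ", sz, " bytes)", call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  head_raw <- readBin(con, "raw", n = min(sz, 512L))
  head_txt <- rawToChar(head_raw[head_raw >= as.raw(32) & head_raw < as.raw(127)])
  is_ascii <- grepl("^\\s*solid", head_txt, useBytes = TRUE) &&
    (grepl("facet", head_txt, fixed = TRUE, useBytes = TRUE) ||
       !any(head_raw == as.raw(0)))
  if (is_ascii) {
    tri <- parse_stl_ascii(path)
  } else {
    if (sz < 84) stop("malformed binary STL: header truncated at byte ", sz, call. = FALSE)
    seek(con, 80)
    nt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    if (nt <= 0) stop("STL contains 0 triangles", call. = FALSE)
    expected <- 84 + 50 * as.numeric(nt)
    if (sz < expected) {
      stop(sprintf("malformed binary STL: expected %d bytes for %d triangles, file ends at byte %d",
                   expected, nt, sz), call. = FALSE)
    }
    r <- readBin(con, "raw", n = 50L * nt)
    dim(r) <- c(50L, nt)
    vr <- r[13:48, , drop = FALSE]     # skip 12-byte normal, take 9 floats
    tri <- matrix(readBin(as.raw(vr), "numeric", size = 4L, n = 9L * nt,
                          endian = "little"), ncol = 3L, byrow = TRUE)
  }
  soup_to_mesh(tri, merge_tolerance)
}

parse_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0L) stop("STL contains 0 triangles", call. = FALSE)
  if (length(vl) %% 3L != 0L) {
    stop("malformed ASCII STL: vertex count ", length(vl),
         " is not a multiple of 3", call. = FALSE)
  }
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(p) as.numeric(p[2:4]))
  tri <- do.call(rbind, nums)
  if (anyNA(tri)) stop("malformed ASCII STL: unparseable vertex line", call. = FALSE)
  tri
}

# tri: (3*nt) x 3 matrix, rows grouped per triangle
soup_to_mesh <- function(tri, tol) {
  key <- paste(round(tri[, 1] / tol), round(tri[, 2] / tol), round(tri[, 3] / tol))
  idx <- match(key, unique(key))
  first <- !duplicated(idx)
  vertices <- tri[first, , drop = FALSE]
  faces <- matrix(idx, ncol = 3L, byrow = TRUE)
  triangle_mesh(vertices, faces)
}

#' @rdname read_stl
#' @param mesh a `sac_mesh` to write.
#' @param format `"binary"` (default) or `"ascii"`.
#' @param name solid name recorded in the file.
#' @export
write_stl <- function(mesh, path, format = c("binary", "ascii"), name = "sacshape") {
  stopifnot(inherits(mesh, "sac_mesh"))
  format <- match.arg(format)
  v <- mesh$vertices
  f <- mesh$faces
  fn <- face_normals(mesh)
  nrm <- sqrt(rowSums(fn^2)); nrm[nrm == 0] <- 1
  fn <- fn / nrm
  nt <- nrow(f)
  if (format == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", paste("binary STL written by", name)))[1:80]
    writeBin(header, con)
    writeBin(as.integer(nt), con, size = 4, endian = "little")
    # interleave: per triangle 12 floats + uint16 attribute
    block <- rbind(t(fn), t(v[f[, 1], , drop = FALSE]),
                   t(v[f[, 2], , drop = FALSE]), t(v[f[, 3], , drop = FALSE]))
    fr <- writeBin(as.numeric(block), raw(), size = 4, endian = "little")
    dim(fr) <- c(48L, nt)
    writeBin(as.raw(rbind(fr, matrix(as.raw(0), 2L, nt))), con)
  } else {
    a <- v[f[, 1], , drop = FALSE]; b <- v[f[, 2], , drop = FALSE]
    c_ <- v[f[, 3], , drop = FALSE]
    txt <- c(
      paste("solid", name),
      as.vector(rbind(
        sprintf(" facet normal %.9g %.9g %.9g", fn[, 1], fn[, 2], fn[, 3]),
        "  outer loop",
        sprintf("   vertex %.9g %.9g %.9g", a[, 1], a[, 2], a[, 3]),
        sprintf("   vertex %.9g %.9g %.9g", b[, 1], b[, 2], b[, 3]),
        sprintf("   vertex %.9g %.9g %.9g", c_[, 1], c_[, 2], c_[, 3]),
        "  endloop",
        " endfacet")),
      paste("endsolid", name))
    writeLines(txt, path)
  }
  invisible(path)
}

#' Export a distance map
#'
#' Writes per-vertex distances as CSV (`vertex_index, distance_mm`) and,
#' optionally, as an ASCII PLY with the distance attached as a per-vertex
#' scalar (`quality`) for heatmap rendering in external viewers.
#'
#' @param dmap a `sac_distance_map`.
#' @param csv_path output CSV path (or `NULL` to skip).
#' @param ply_path output PLY path (requires `mesh`).
#' @param mesh the query `sac_mesh` the distances belong to.
#' @return invisibly, the paths written.
#' @export
export_distance_map <- function(dmap, csv_path = NULL, ply_path = NULL, mesh = NULL) {
  written <- character()
  if (!is.null(csv_path)) {
    utils::write.csv(
      data.frame(vertex_index = dmap$vertex, distance_mm = dmap$distance_mm),
      csv_path, row.names = FALSE)
    written <- c(written, csv_path)
  }
  if (!is.null(ply_path)) {
    if (is.null(mesh)) stop("PLY export needs the query mesh", call. = FALSE)
    v <- mesh$vertices; f <- mesh$faces
    txt <- c(
      "ply", "format ascii 1.0",
      sprintf("element vertex %d", nrow(v)),
      "property float x", "property float y", "property float z",
      "property float quality",
      sprintf("element face %d", nrow(f)),
      "property list uchar int vertex_indices", "end_header",
      sprintf("%.6f %.6f %.6f %.6f", v[, 1], v[, 2], v[, 3], dmap$distance_mm),
      sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L))
    writeLines(txt, ply_path)
    written <- c(written, ply_path)
  }
  invisible(written)
}
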