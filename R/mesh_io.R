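#' Read a triangulated surface mesh
#'
#' Reads STL (binary or ASCII), PLY (ASCII), OBJ, or VTP (ASCII XML
#' PolyData) files into a [tri_surface()]. Coordinates are taken verbatim and
#' are assumed to be world millimetres. The mesh is cleaned on load:
#' duplicate vertices merged at `merge_tol`, degenerate triangles dropped,
#' boundary loops computed. Non-manifold input raises an error naming
#' offending edges.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"stl"`, `"ply"`, `"obj"`, `"vtp"`;
#'   `"auto"` uses the file extension.
#' @param merge_tol vertex merge tolerance (mm).
#' @return a [tri_surface()].
#' @export
read_surface <- function(path, format = c("auto", "stl", "ply", "obj", "vtp"),
                         merge_tol = 1e-6) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("stl", "ply", "obj", "vtp"))
      stop("cannot auto-detect mesh format from extension: ", path)
  }
  raw <- switch(format,
    stl = read_stl(path),
    ply = read_ply(path),
    obj = read_obj(path),
    vtp = read_vtp(path))
  tri_surface(raw$vertices, raw$faces, clean = TRUE, merge_tol = merge_tol)
}

#' Write a triangulated surface mesh
#'
#' @param surface a [tri_surface()].
#' @param path output path.
#' @param format `"auto"` (from extension), `"stl"` (ASCII), `"stl_binary"`,
#'   `"ply"`, `"obj"`, or `"vtp"`.
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path,
                          format = c("auto", "stl", "stl_binary", "ply", "obj", "vtp")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("stl", "ply", "obj", "vtp"))
      stop("cannot auto-detect mesh format from extension: ", path)
  }
  v <- surface$vertices
  f <- surface$faces
  switch(format,
    stl = write_stl_ascii(v, f, path),
    stl_binary = write_stl_binary(v, f, path),
    ply = write_ply(v, f, path),
    obj = write_obj(v, f, path),
    vtp = write_vtp(v, f, path))
  invisible(path)
}

# ---- STL ----

stl_is_binary <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 80L)
  if (sz < 84L) return(FALSE)
  ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  # binary files have exactly 84 + 50 * ntri bytes
  isTRUE(sz == 84 + 50 * as.numeric(ntri))
}

read_stl <- function(path) {
  if (stl_is_binary(path)) read_stl_binary(path) else read_stl_ascii(path)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80L)
  ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  rec <- readBin(con, "raw", 50L * ntri)
  m <- matrix(rec, nrow = 50L)
  vals <- readBin(as.vector(m[1:48, ]), "numeric", size = 4L,
                  n = 12L * ntri, endian = "little")
  vals <- matrix(vals, ncol = 12L, byrow = TRUE)  # normal + 3 vertices
  verts <- rbind(vals[, 4:6, drop = FALSE], vals[, 7:9, drop = FALSE],
                 vals[, 10:12, drop = FALSE])
  ord <- as.vector(t(matrix(seq_len(3L * ntri), ncol = 3L)))
  verts <- verts[ord, , drop = FALSE]
  faces <- matrix(seq_len(3L * ntri), ncol = 3L, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    stop("cannot parse ASCII STL: ", path)
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(x) as.numeric(x[2:4]))
  verts <- do.call(rbind, nums)
  faces <- matrix(seq_len(nrow(verts)), ncol = 3L, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

write_stl_ascii <- function(v, f, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid mesh", con)
  n <- triangle_normals(v, f)
  for (i in seq_len(nrow(f))) {
    writeLines(sprintf("  facet normal %.9g %.9g %.9g", n[i, 1], n[i, 2], n[i, 3]), con)
    writeLines("    outer loop", con)
    for (j in 1:3) {
      p <- v[f[i, j], ]
      writeLines(sprintf("      vertex %.9g %.9g %.9g", p[1], p[2], p[3]), con)
    }
    writeLines("    endloop", con)
    writeLines("  endfacet", con)
  }
  writeLines("endsolid mesh", con)
}

write_stl_binary <- function(v, f, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80L), con)
  writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
  n <- triangle_normals(v, f)
  for (i in seq_len(nrow(f))) {
    writeBin(as.numeric(c(n[i, ], t(v[f[i, ], ]))), con, size = 4L,
             endian = "little")
    writeBin(raw(2L), con)
  }
}

triangle_normals <- function(v, f) {
  u <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  w <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
             u[, 3] * w[, 1] - u[, 1] * w[, 3],
             u[, 1] * w[, 2] - u[, 2] * w[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

# ---- PLY (ASCII) ----

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^ply", lines[1])) stop("not a PLY file: ", path)
  endh <- match("end_header", trimws(lines))
  if (is.na(endh)) stop("PLY header not terminated: ", path)
  header <- trimws(lines[seq_len(endh)])
  if (!any(grepl("^format\\s+ascii", header)))
    stop("only ASCII PLY is supported: ", path)
  nv <- as.integer(sub("^element\\s+vertex\\s+", "",
                       grep("^element\\s+vertex", header, value = TRUE)[1]))
  nf <- as.integer(sub("^element\\s+face\\s+", "",
                       grep("^element\\s+face", header, value = TRUE)[1]))
  body <- lines[(endh + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  vparts <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  verts <- do.call(rbind, lapply(vparts, function(x) as.numeric(x[1:3])))
  fparts <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  faces <- do.call(rbind, lapply(fparts, function(x) {
    k <- as.integer(x[1])
    if (k != 3L) stop("only triangular PLY faces are supported")
    as.integer(x[2:4]) + 1L
  }))
  list(vertices = verts, faces = faces)
}

write_ply <- function(v, f, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
}

# ---- OBJ ----

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                 function(x) as.numeric(x[2:4])))
  faces <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(x) {
    idx <- as.integer(sub("/.*$", "", x[-1]))
    if (length(idx) != 3L) stop("only triangular OBJ faces are supported")
    if (any(idx < 0L)) stop("negative OBJ indices are not supported")
    idx
  }))
  list(vertices = verts, faces = faces)
}

write_obj <- function(v, f, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
}

# ---- VTP (ASCII XML PolyData) ----

read_vtp <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  pts <- xml2::xml_find_first(piece, ".//Points/DataArray")
  if (!identical(xml2::xml_attr(pts, "format"), "ascii"))
    stop("only ascii-format VTP is supported: ", path)
  coords <- as.numeric(strsplit(trimws(xml2::xml_text(pts)), "\\s+")[[1]])
  verts <- matrix(coords, ncol = 3L, byrow = TRUE)
  conn <- xml2::xml_find_first(piece, ".//Polys/DataArray[@Name='connectivity']")
  offs <- xml2::xml_find_first(piece, ".//Polys/DataArray[@Name='offsets']")
  ci <- as.integer(strsplit(trimws(xml2::xml_text(conn)), "\\s+")[[1]])
  oi <- as.integer(strsplit(trimws(xml2::xml_text(offs)), "\\s+")[[1]])
  if (any(diff(c(0L, oi)) != 3L)) stop("only triangular VTP polys are supported")
  faces <- matrix(ci, ncol = 3L, byrow = TRUE) + 1L
  list(vertices = verts, faces = faces)
}

write_vtp <- function(v, f, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines('<?xml version="1.0"?>', con)
  writeLines('<VTKFile type="PolyData" version="0.1" byte_order="LittleEndian">', con)
  writeLines("  <PolyData>", con)
  writeLines(sprintf('    <Piece NumberOfPoints="%d" NumberOfVerts="0" NumberOfLines="0" NumberOfStrips="0" NumberOfPolys="%d">',
                     nrow(v), nrow(f)), con)
  writeLines("      <Points>", con)
  writeLines('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">', con)
  writeLines(paste("         ", sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3])), con)
  writeLines("        </DataArray>", con)
  writeLines("      </Points>", con)
  writeLines("      <Polys>", con)
  writeLines('        <DataArray type="Int64" Name="connectivity" format="ascii">', con)
  writeLines(paste("         ", sprintf("%d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)), con)
  writeLines("        </DataArray>", con)
  writeLines('        <DataArray type="Int64" Name="offsets" format="ascii">', con)
  writeLines(paste("         ", paste(seq_len(nrow(f)) * 3L, collapse = " ")), con)
  writeLines("        </DataArray>", con)
  writeLines("      </Polys>", con)
  writeLines("    </Piece>", con)
  writeLines("  </PolyData>", con)
  writeLines("</VTKFile>", con)
}

#' Export polylines as a VTP file
#'
#' Writes a set of 3D polylines (e.g. isolines, centerline, curvature paths)
#' as ASCII XML PolyData with `Lines` connectivity.
#'
#' @param polylines list of numeric matrices (n x 3), one per polyline.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vtp_polylines <- function(polylines, path) {
  pts <- do.call(rbind, polylines)
  n_per <- vapply(polylines, nrow, integer(1))
  offs <- cumsum(n_per)
  starts <- c(0L, offs[-length(offs)])
  conn <- unlist(lapply(seq_along(polylines),
                        function(i) seq.int(starts[i], offs[i] - 1L)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines('<?xml version="1.0"?>', con)
  writeLines('<VTKFile type="PolyData" version="0.1" byte_order="LittleEndian">', con)
  writeLines("  <PolyData>", con)
  writeLines(sprintf('    <Piece NumberOfPoints="%d" NumberOfVerts="0" NumberOfLines="%d" NumberOfStrips="0" NumberOfPolys="0">',
                     nrow(pts), length(polylines)), con)
  writeLines("      <Points>", con)
  writeLines('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">', con)
  writeLines(paste("         ", sprintf("%.9g %.9g %.9g", pts[, 1], pts[, 2], pts[, 3])), con)
  writeLines("        </DataArray>", con)
  writeLines("      </Points>", con)
  writeLines("      <Lines>", con)
  writeLines('        <DataArray type="Int64" Name="connectivity" format="ascii">', con)
  writeLines(paste("         ", paste(conn, collapse = " ")), con)
  writeLines("        </DataArray>", con)
  writeLines('        <DataArray type="Int64" Name="offsets" format="ascii">', con)
  writeLines(paste("         ", paste(offs, collapse = " ")), con)
  writeLines("        </DataArray>", con)
  writeLines("      </Lines>", con)
  writeLines("    </Piece>", con)
  writeLines("  </PolyData>", con)
  writeLines("</VTKFile>", con)
  invisible(path)
}
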