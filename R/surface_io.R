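#' Read a triangle surface mesh from OBJ, STL or PLY
#'
#' OBJ group tags (`g`) populate `face_groups`; STL files (ASCII or binary)
#' are welded at `weld_tol` since the format stores per-facet vertices; PLY
#' support covers the ASCII dialect.
#'
#' @param path file path.
#' @param format `"auto"` (from extension) or one of `"obj"`, `"stl"`, `"ply"`.
#' @param weld_tol STL vertex welding tolerance in mm (default `1e-6`).
#' @return a [surface_mesh].
#' @export
read_surface <- function(path, format = c("auto", "obj", "stl", "ply"),
                         weld_tol = 1e-6) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("obj", "stl", "ply")) {
      stop(sprintf("cannot infer surface format from extension of '%s'", path),
           call. = FALSE)
    }
  }
  switch(format,
         obj = read_obj(path),
         stl = read_stl(path, weld_tol = weld_tol),
         ply = read_ply(path))
}

#' Write a triangle surface mesh
#'
#' @param mesh a [surface_mesh].
#' @param path output file path.
#' @param format `"auto"` (from extension) or one of `"obj"`, `"stl"`, `"ply"`.
#' @param binary for STL, write the binary dialect (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_surface <- function(mesh, path, format = c("auto", "obj", "stl", "ply"),
                          binary = TRUE) {
  format <- match.arg(format)
  if (format == "auto") format <- tolower(tools::file_ext(path))
  switch(format,
         obj = write_obj(mesh, path),
         stl = write_stl(mesh, path, binary = binary),
         ply = write_ply(mesh, path),
         stop(sprintf("unsupported surface format '%s'", format), call. = FALSE))
  invisible(path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  verts <- list(); faces <- list(); groups <- list()
  cur_group <- NA_character_
  for (li in seq_along(toks)) {
    tk <- toks[[li]]
    if (length(tk) == 0 || tk[1] == "") next
    if (tk[1] == "v") {
      if (length(tk) < 4) stop(sprintf("OBJ parse error at line %d: short vertex record", li), call. = FALSE)
      verts[[length(verts) + 1L]] <- as.numeric(tk[2:4])
    } else if (tk[1] == "g") {
      cur_group <- if (length(tk) > 1) tk[2] else NA_character_
    } else if (tk[1] == "f") {
      idx <- suppressWarnings(as.integer(sub("/.*$", "", tk[-1])))
      if (anyNA(idx) || length(idx) < 3) {
        stop(sprintf("OBJ parse error at line %d: bad face record", li), call. = FALSE)
      }
      # fan-triangulate polygons
      for (k in seq_len(length(idx) - 2L)) {
        faces[[length(faces) + 1L]] <- idx[c(1L, k + 1L, k + 2L)]
        groups[[length(groups) + 1L]] <- cur_group
      }
    }
  }
  v <- do.call(rbind, verts)
  f <- if (length(faces)) do.call(rbind, faces) else matrix(integer(0), 0, 3)
  if (nrow(f) > 0 && any(f < 1L | f > nrow(v))) {
    bad <- which(f < 1L | f > nrow(v), arr.ind = TRUE)
    stop(sprintf("OBJ face index out of range (faces: %s); OBJ indices are 1-based",
                 paste(unique(bad[, 1]), collapse = ", ")), call. = FALSE)
  }
  g <- unlist(groups)
  if (all(is.na(g))) g <- NULL else g <- as.integer(factor(g, exclude = NULL))
  surface_mesh(v, f, face_groups = g)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.17g %.17g %.17g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  f <- mesh$faces
  if (is.null(mesh$face_groups)) {
    writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  } else {
    for (gr in unique(mesh$face_groups)) {
      writeLines(sprintf("g group_%s", gr), con)
      sel <- which(mesh$face_groups == gr)
      writeLines(sprintf("f %d %d %d", f[sel, 1], f[sel, 2], f[sel, 3]), con)
    }
  }
  invisible(path)
}

read_stl <- function(path, weld_tol = 1e-6) {
  # Sniff ASCII vs binary: ASCII files start with "solid" and contain "facet"
  head_raw <- readBin(path, "raw", n = 512)
  printable <- head_raw >= as.raw(0x20) & head_raw <= as.raw(0x7e) |
    head_raw %in% as.raw(c(0x09, 0x0a, 0x0d))
  head_txt <- rawToChar(head_raw[printable])
  is_ascii <- grepl("^\\s*solid", head_txt, useBytes = TRUE) &&
    grepl("facet", head_txt, useBytes = TRUE)
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
  nv <- nrow(tri)
  if (nv %% 3 != 0) stop("STL parse error: vertex count not a multiple of 3", call. = FALSE)
  mesh <- surface_mesh(tri, matrix(seq_len(nv), ncol = 3, byrow = TRUE),
                       validate = FALSE)
  weld_vertices(mesh, tol = weld_tol)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  toks <- strsplit(trimws(vl), "[[:space:]]+")
  bad <- which(vapply(toks, length, 1L) < 4)
  if (length(bad) > 0) {
    stop(sprintf("STL parse error: short vertex record %d", bad[1]), call. = FALSE)
  }
  do.call(rbind, lapply(toks, function(tk) as.numeric(tk[2:4])))
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  ntri <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (is.na(ntri) || ntri < 0) stop("STL parse error: bad triangle count", call. = FALSE)
  out <- matrix(NA_real_, ntri * 3, 3)
  for (t in seq_len(ntri)) {
    rec <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
    if (length(rec) < 12) stop(sprintf("STL parse error: truncated record %d", t), call. = FALSE)
    out[(3 * t - 2):(3 * t), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
    readBin(con, "raw", n = 2)
  }
  out
}

write_stl <- function(mesh, path, binary = TRUE) {
  v <- mesh$vertices; f <- mesh$faces
  n <- face_normals(mesh)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (t in seq_len(nrow(f))) {
      writeBin(as.numeric(c(n[t, ], t(v[f[t, ], ]))), con, size = 4,
               endian = "little")
      writeBin(raw(2), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid mesh", con)
    for (t in seq_len(nrow(f))) {
      writeLines(sprintf("  facet normal %.9g %.9g %.9g", n[t, 1], n[t, 2], n[t, 3]), con)
      writeLines("    outer loop", con)
      for (k in 1:3) {
        writeLines(sprintf("      vertex %.17g %.17g %.17g",
                           v[f[t, k], 1], v[f[t, k], 2], v[f[t, k], 3]), con)
      }
      writeLines("    endloop", con)
      writeLines("  endfacet", con)
    }
    writeLines("endsolid mesh", con)
  }
  invisible(path)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  endh <- match("end_header", trimws(lines))
  if (is.na(endh)) stop("PLY parse error: no end_header", call. = FALSE)
  header <- trimws(lines[seq_len(endh)])
  fmt <- grep("^format", header, value = TRUE)
  if (!any(grepl("ascii", fmt))) {
    stop("PLY parse error: only the ascii format is supported", call. = FALSE)
  }
  nvert <- as.integer(sub("^element vertex\\s+", "",
                          grep("^element vertex", header, value = TRUE)))
  nface <- as.integer(sub("^element face\\s+", "",
                          grep("^element face", header, value = TRUE)))
  if (length(nvert) != 1 || length(nface) != 1 || is.na(nvert) || is.na(nface)) {
    stop("PLY parse error: missing vertex/face element counts", call. = FALSE)
  }
  body <- lines[(endh + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  vt <- strsplit(trimws(body[seq_len(nvert)]), "[[:space:]]+")
  v <- do.call(rbind, lapply(vt, function(tk) as.numeric(tk[1:3])))
  ft <- strsplit(trimws(body[nvert + seq_len(nface)]), "[[:space:]]+")
  faces <- list()
  for (tk in ft) {
    k <- as.integer(tk[1])
    idx <- as.integer(tk[2:(1 + k)]) + 1L  # PLY is 0-based
    for (q in seq_len(k - 2L)) faces[[length(faces) + 1L]] <- idx[c(1L, q + 1L, q + 2L)]
  }
  f <- if (length(faces)) do.call(rbind, faces) else matrix(integer(0), 0, 3)
  surface_mesh(v, f)
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.17g %.17g %.17g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                     mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  invisible(path)
}
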