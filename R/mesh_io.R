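# Triangle-mesh container and file I/O (PLY ascii/binary, OBJ, ASCII STL).
# No pre-installed R package reads PLY, so a minimal reader/writer lives here.

#' Triangular surface mesh
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices,
#'   counter-clockwise winding.
#' @param normals Optional n x 3 per-vertex unit normals; computed
#'   area-weighted from faces when absent and faces exist.
#' @param grid Optional height-field grid metadata (internal, set by
#'   [reconstruct_surface()]); enables fast point location.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, normals = NULL, grid = NULL) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 3, all(is.finite(vertices)))
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) > 0) {
    stopifnot(min(faces) >= 1, max(faces) <= nrow(vertices))
    a <- face_areas(vertices, faces)
    if (any(a <= 1e-12)) stop("degenerate faces (area <= 1e-12 mm^2)")
  }
  if (is.null(normals) && nrow(faces) > 0) {
    normals <- vertex_normals(vertices, faces)
  } else if (!is.null(normals)) {
    normals <- as.matrix(normals)
    stopifnot(nrow(normals) == nrow(vertices), ncol(normals) == 3)
    len <- sqrt(rowSums(normals^2))
    normals <- normals / len
  }
  structure(list(vertices = vertices, faces = faces, normals = normals,
                 grid = grid),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (!is.null(x$grid)) " (height-field grid)" else ""))
  invisible(x)
}

face_areas <- function(V, F) {
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

# area-weighted per-vertex normals
vertex_normals <- function(V, F) {
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])  # 2*area-weighted
  N <- matrix(0, nrow(V), 3)
  for (k in 1:3) {
    acc <- rowsum(fn, group = F[, k])
    ids <- as.integer(rownames(acc))
    N[ids, ] <- N[ids, ] + acc
  }
  len <- sqrt(rowSums(N^2))
  len[len == 0] <- 1
  N / len
}

#' Read a mesh or point cloud (PLY, OBJ, ASCII STL)
#'
#' Format chosen by extension. PLY supports ascii 1.0 and
#' binary_little_endian 1.0 with x/y/z (float or double) vertex properties
#' and optional nx/ny/nz; faces are triangles. Units are millimetres.
#' Malformed or truncated files raise a format error naming the offending
#' line/offset.
#'
#' @param path Input file.
#' @return A `surface_mesh` (possibly with zero faces: a point cloud).
#' @export
load_scan <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = read_ply(path),
         obj = read_obj(path),
         stl = read_stl_ascii(path),
         stop("unsupported mesh format: .", ext))
}

#' Write a mesh (ASCII PLY or OBJ)
#' @param mesh A `surface_mesh` (or a list with `vertices`, `faces`,
#'   optionally `normals`).
#' @param path Output file; extension selects the format.
#' @rdname load_scan
#' @export
save_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = write_ply_ascii(mesh, path),
         obj = write_obj(mesh, path),
         stl = write_stl_ascii(mesh, path),
         stop("unsupported mesh format: .", ext))
  invisible(path)
}

#' @rdname load_scan
#' @export
write_mesh <- save_mesh

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!identical(magic, "ply")) stop("format error in ", path, ": missing 'ply' magic at line 1")
  fmt <- NULL; nv <- NULL; nf <- 0
  vprops <- character(0)
  in_vertex <- FALSE; in_face <- FALSE
  lineno <- 1
  repeat {
    ln <- readLines(con, n = 1)
    lineno <- lineno + 1
    if (length(ln) == 0) stop("format error in ", path, ": header ended prematurely at line ", lineno)
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 0) next
    if (tok[1] == "format") {
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      in_vertex <- tok[2] == "vertex"
      in_face <- tok[2] == "face"
      if (in_vertex) nv <- as.integer(tok[3])
      if (in_face) nf <- as.integer(tok[3])
    } else if (tok[1] == "property" && in_vertex && tok[2] != "list") {
      vprops <- c(vprops, paste(tok[2], tok[3]))
    } else if (tok[1] == "end_header") break
  }
  if (is.null(fmt) || is.null(nv)) stop("format error in ", path, ": incomplete PLY header")
  pnames <- vapply(strsplit(vprops, " "), `[`, character(1), 2)
  ptypes <- vapply(strsplit(vprops, " "), `[`, character(1), 1)
  need <- c("x", "y", "z")
  if (!all(need %in% pnames)) stop("format error in ", path, ": vertex needs x,y,z properties")
  if (fmt == "ascii") {
    vl <- readLines(con, n = nv)
    if (length(vl) < nv) stop("format error in ", path, ": truncated vertex block (line ",
                              lineno + length(vl), ")")
    vm <- matrix(as.numeric(unlist(strsplit(trimws(vl), "\\s+"))),
                 nrow = nv, byrow = TRUE)
    if (anyNA(vm)) stop("format error in ", path, ": non-numeric vertex data")
    V <- vm[, match(need, pnames), drop = FALSE]
    N <- if (all(c("nx", "ny", "nz") %in% pnames)) {
      vm[, match(c("nx", "ny", "nz"), pnames), drop = FALSE]
    } else NULL
    F <- NULL
    if (nf > 0) {
      fl <- readLines(con, n = nf)
      if (length(fl) < nf) stop("format error in ", path, ": truncated face block")
      F <- t(vapply(strsplit(trimws(fl), "\\s+"), function(tk) {
        k <- as.integer(tk[1])
        if (is.na(k) || k != 3) stop("format error in ", path, ": only triangle faces supported")
        as.integer(tk[2:4]) + 1L
      }, integer(3)))
    }
  } else if (fmt == "binary_little_endian") {
    sizes <- c(float = 4L, float32 = 4L, double = 8L, float64 = 8L)
    if (!all(ptypes %in% names(sizes))) {
      stop("format error in ", path, ": unsupported binary vertex property types")
    }
    vm <- matrix(NA_real_, nv, length(pnames))
    for (i in seq_len(nv)) {
      for (j in seq_along(pnames)) {
        b <- readBin(con, "numeric", n = 1, size = sizes[[ptypes[j]]],
                     endian = "little")
        if (length(b) == 0) stop("format error in ", path, ": truncated binary vertex data at vertex ", i)
        vm[i, j] <- b
      }
    }
    V <- vm[, match(need, pnames), drop = FALSE]
    N <- if (all(c("nx", "ny", "nz") %in% pnames)) {
      vm[, match(c("nx", "ny", "nz"), pnames), drop = FALSE]
    } else NULL
    F <- NULL
    if (nf > 0) {
      F <- matrix(NA_integer_, nf, 3)
      for (i in seq_len(nf)) {
        k <- readBin(con, "integer", n = 1, size = 1, signed = FALSE)
        if (length(k) == 0 || k != 3) stop("format error in ", path, ": bad binary face at ", i)
        ix <- readBin(con, "integer", n = 3, size = 4, endian = "little")
        if (length(ix) < 3) stop("format error in ", path, ": truncated binary face data")
        F[i, ] <- ix + 1L
      }
    }
  } else stop("format error in ", path, ": unsupported PLY format '", fmt, "'")
  if (is.null(F)) F <- matrix(integer(0), 0, 3)
  surface_mesh(V, F, normals = N)
}

write_ply_ascii <- function(mesh, path) {
  V <- mesh$vertices; F <- mesh$faces; N <- mesh$normals
  has_n <- !is.null(N)
  hdr <- c("ply", "format ascii 1.0",
           "comment units mm; euler convention intrinsic Z-Y-X",
           sprintf("element vertex %d", nrow(V)),
           "property double x", "property double y", "property double z")
  if (has_n) hdr <- c(hdr, "property double nx", "property double ny", "property double nz")
  hdr <- c(hdr, sprintf("element face %d", nrow(F)),
           "property list uchar int vertex_indices", "end_header")
  vd <- if (has_n) cbind(V, N) else V
  vlines <- apply(vd, 1, function(r) paste(format(r, digits = 17, trim = TRUE), collapse = " "))
  flines <- if (nrow(F) > 0) {
    apply(F, 1, function(r) paste(c(3L, r - 1L), collapse = " "))
  } else character(0)
  writeLines(c(hdr, vlines, flines), path)
}

#' Write a binary little-endian PLY (round-trip fixture support)
#' @inheritParams save_mesh
#' @export
write_ply_binary <- function(mesh, path) {
  V <- mesh$vertices; F <- mesh$faces; N <- mesh$normals
  has_n <- !is.null(N)
  hdr <- c("ply", "format binary_little_endian 1.0",
           sprintf("element vertex %d", nrow(V)),
           "property double x", "property double y", "property double z")
  if (has_n) hdr <- c(hdr, "property double nx", "property double ny", "property double nz")
  hdr <- c(hdr, sprintf("element face %d", nrow(F)),
           "property list uchar int vertex_indices", "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  vd <- if (has_n) cbind(V, N) else V
  for (i in seq_len(nrow(vd))) {
    writeBin(as.numeric(vd[i, ]), con, size = 8, endian = "little")
  }
  for (i in seq_len(nrow(F))) {
    writeBin(as.raw(3L), con)
    writeBin(as.integer(F[i, ] - 1L), con, size = 4, endian = "little")
  }
  invisible(path)
}

read_obj <- function(path) {
  lines <- readLines(path)
  vt <- grepl("^v\\s", lines)
  ft <- grepl("^f\\s", lines)
  V <- if (any(vt)) {
    vm <- strsplit(trimws(sub("^v", "", lines[vt])), "\\s+")
    bad <- which(vapply(vm, length, integer(1)) < 3)
    if (length(bad)) stop("format error in ", path, ": bad vertex at line ",
                          which(vt)[bad[1]])
    m <- t(vapply(vm, function(x) as.numeric(x[1:3]), numeric(3)))
    if (anyNA(m)) stop("format error in ", path, ": non-numeric vertex")
    m
  } else stop("format error in ", path, ": no vertices")
  F <- if (any(ft)) {
    fm <- strsplit(trimws(sub("^f", "", lines[ft])), "\\s+")
    t(vapply(fm, function(x) {
      ix <- as.integer(sub("/.*", "", x))
      if (length(ix) != 3 || anyNA(ix)) stop("format error in ", path, ": non-triangle face")
      ix
    }, integer(3)))
  } else matrix(integer(0), 0, 3)
  surface_mesh(V, F)
}

write_obj <- function(mesh, path) {
  V <- mesh$vertices; F <- mesh$faces
  vlines <- apply(V, 1, function(r) paste("v", paste(format(r, digits = 17, trim = TRUE), collapse = " ")))
  flines <- if (nrow(F) > 0) apply(F, 1, function(r) paste("f", paste(r, collapse = " "))) else character(0)
  writeLines(c("# units mm", vlines, flines), path)
}

read_stl_ascii <- function(path) {
  lines <- trimws(readLines(path))
  if (!length(lines) || !grepl("^solid", lines[1])) {
    stop("format error in ", path, ": not an ASCII STL (missing 'solid')")
  }
  vl <- grep("^vertex\\s", lines, value = TRUE)
  if (length(vl) %% 3 != 0) stop("format error in ", path, ": vertex count not a multiple of 3")
  if (!any(grepl("^endsolid", lines))) stop("format error in ", path, ": truncated (no 'endsolid')")
  V <- t(vapply(strsplit(sub("^vertex\\s+", "", vl), "\\s+"),
                function(x) as.numeric(x[1:3]), numeric(3)))
  if (anyNA(V)) stop("format error in ", path, ": non-numeric vertex")
  nf <- nrow(V) / 3
  F <- matrix(seq_len(3 * nf), ncol = 3, byrow = TRUE)
  surface_mesh(V, F)
}

write_stl_ascii <- function(mesh, path) {
  V <- mesh$vertices; F <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid woundpath", con)
  for (i in seq_len(nrow(F))) {
    tri <- V[F[i, ], , drop = FALSE]
    e1 <- tri[2, ] - tri[1, ]; e2 <- tri[3, ] - tri[1, ]
    n <- c(e1[2] * e2[3] - e1[3] * e2[2],
           e1[3] * e2[1] - e1[1] * e2[3],
           e1[1] * e2[2] - e1[2] * e2[1])
    n <- n / max(sqrt(sum(n^2)), 1e-300)
    writeLines(sprintf("facet normal %.9g %.9g %.9g", n[1], n[2], n[3]), con)
    writeLines("outer loop", con)
    for (k in 1:3) {
      writeLines(sprintf("vertex %.17g %.17g %.17g", tri[k, 1], tri[k, 2], tri[k, 3]), con)
    }
    writeLines(c("endloop", "endfacet"), con)
  }
  writeLines("endsolid woundpath", con)
}
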