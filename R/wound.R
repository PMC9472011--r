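# Wound-surface reconstruction and defect-volume computation.
#
# A structured-light scan of the wound area is an open surface, not a solid,
# so the "defect model" is expressed as the region between two surfaces over
# a shared triangulation: the wound bed (the scan inside the rim) and a cap
# (the interpolated healthy surface spanning the rim). The defect volume is
# the prismatic integral of cap-minus-bed; bioink is allocated from it.

#' Reconstruct a height-field surface from a point cloud
#'
#' Regular-grid height-field triangulation: grid nodes at `grid_step` pitch
#' span the cloud's (x, y) footprint, each node's height comes from a local
#' least-squares plane fit of the points in its neighbourhood (which
#' reproduces planar surfaces exactly), and nodes are joined into a regular
#' triangle mesh with area-weighted vertex normals.
#'
#' The cloud must be height-field-like: one surface sheet per (x, y) after
#' orientation. Folded clouds (a cell whose points span a tall z-range)
#' raise an ambiguity error suggesting re-orientation; `orient = "auto"`
#' first rotates the cloud so its total-least-squares plane normal points
#' along +z.
#'
#' @param cloud An n x 3 point matrix (mm) or a zero-face `surface_mesh`.
#' @param grid_step Grid pitch, mm.
#' @param orient `"none"` (default) or `"auto"`.
#' @param neighbourhood Fit radius in multiples of `grid_step` (default 1.6).
#' @return A `surface_mesh` with height-field grid metadata.
#' @export
reconstruct_surface <- function(cloud, grid_step, orient = c("none", "auto"),
                                neighbourhood = 1.6) {
  orient <- match.arg(orient)
  P <- if (inherits(cloud, "surface_mesh")) cloud$vertices else as.matrix(cloud)
  stopifnot(ncol(P) == 3, grid_step > 0)
  if (nrow(P) < 3) stop("ambiguity error: need at least 3 points to define a surface")
  orient_rt <- rt_identity()
  if (orient == "auto") {
    pl <- fit_plane(P)
    z <- c(0, 0, 1)
    v <- c(pl$normal[2] * z[3] - pl$normal[3] * z[2],
           pl$normal[3] * z[1] - pl$normal[1] * z[3],
           pl$normal[1] * z[2] - pl$normal[2] * z[1])
    s <- sqrt(sum(v^2)); cth <- sum(pl$normal * z)
    R <- if (s < 1e-12) diag(3) else {
      K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
      diag(3) + K + K %*% K * ((1 - cth) / s^2)
    }
    ctr <- colMeans(P)
    orient_rt <- rigid_transform(R, -as.numeric(R %*% ctr), tol = 1e-6)
    P <- rt_apply(orient_rt, P)
  }

  xs <- seq(min(P[, 1]), max(P[, 1]), by = grid_step)
  ys <- seq(min(P[, 2]), max(P[, 2]), by = grid_step)
  nx <- length(xs); ny <- length(ys)
  if (nx < 2 || ny < 2) stop("ambiguity error: cloud footprint degenerates to a line; re-orient the scan")

  # bin points into grid cells for neighbour queries
  ci <- pmin(pmax(1L, findInterval(P[, 1], xs)), nx)
  cj <- pmin(pmax(1L, findInterval(P[, 2], ys)), ny)
  cell_of <- (cj - 1L) * nx + ci
  # folded-surface check: z-range inside any one cell
  zr <- tapply(P[, 3], cell_of, function(z) diff(range(z)))
  zspan <- diff(range(P[, 3]))
  if (zspan > 0 && any(zr > max(10 * grid_step, 0.6 * zspan))) {
    stop("ambiguity error: cloud is not a height field over (x, y); re-orient the scan (orient = \"auto\")")
  }
  bins <- split(seq_len(nrow(P)), cell_of)

  rad <- neighbourhood * grid_step
  Z <- matrix(NA_real_, ny, nx)
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      ids <- integer(0)
      for (dj in -1:1) {
        for (di in -1:1) {
          ii <- i + di; jj <- j + dj
          if (ii >= 1 && ii <= nx && jj >= 1 && jj <= ny) {
            b <- bins[[as.character((jj - 1L) * nx + ii)]]
            if (!is.null(b)) ids <- c(ids, b)
          }
        }
      }
      if (!length(ids)) next
      dx <- P[ids, 1] - xs[i]; dy <- P[ids, 2] - ys[j]
      d2 <- dx * dx + dy * dy
      sel <- d2 <= rad * rad
      if (sum(sel) < 3) {
        # sparse spot: widen to the nearest points of the 3x3 neighbourhood
        if (length(ids) < 3) next
        sel <- rank(d2, ties.method = "first") <= min(length(ids), 12)
      }
      dxs <- dx[sel]; dys <- dy[sel]; zs <- P[ids[sel], 3]
      A <- cbind(1, dxs, dys)
      AtA <- crossprod(A)
      coef <- tryCatch(solve(AtA, crossprod(A, zs)),
                       error = function(e) c(mean(zs), 0, 0))
      Z[j, i] <- coef[1]
    }
  }
  build_grid_mesh(xs, ys, Z, orient_rt)
}

# assemble a surface_mesh from a height grid (NA = undefined node)
build_grid_mesh <- function(xs, ys, Z, orient_rt = rt_identity(),
                            normals = NULL) {
  nx <- length(xs); ny <- length(ys)
  idx <- matrix(NA_integer_, ny, nx)
  def <- which(!is.na(Z))
  idx[def] <- seq_along(def)
  jj <- ((def - 1L) %/% ny) + 1L   # column (x index)
  ii <- ((def - 1L) %% ny) + 1L    # row (y index)
  V <- cbind(x = xs[jj], y = ys[ii], z = Z[def])
  faces <- list()
  for (j in seq_len(nx - 1)) {
    for (i in seq_len(ny - 1)) {
      a <- idx[i, j]; b <- idx[i, j + 1]; c <- idx[i + 1, j + 1]; d <- idx[i + 1, j]
      if (!is.na(a) && !is.na(b) && !is.na(c)) faces[[length(faces) + 1]] <- c(a, b, c)
      if (!is.na(a) && !is.na(c) && !is.na(d)) faces[[length(faces) + 1]] <- c(a, c, d)
    }
  }
  F <- if (length(faces)) do.call(rbind, faces) else matrix(integer(0), 0, 3)
  grid <- list(xs = xs, ys = ys, Z = Z, idx = idx,
               step = if (nx > 1) xs[2] - xs[1] else NA_real_,
               orient = orient_rt)
  surface_mesh(V, F, normals = normals, grid = grid)
}

#' Extract the wound model (bed, rim, cap, volume) from a surface
#'
#' The scan shows the wound as a depressed region in an otherwise healthy
#' surface. A reference plane is fitted to the mesh's outer-boundary nodes;
#' nodes deeper than `depth_threshold` below it are wound candidates, the
#' largest connected component becomes the wound bed footprint, and the ring
#' of healthy nodes surrounding it is the rim loop. The cap — the
#' interpolated healthy surface over the wound — solves the Laplace equation
#' on the footprint with rim heights as Dirichlet data (harmonic
#' interpolation; the surrounding surface carries smoothly across the
#' defect). Supplying `rim_polygon` (k x 2, mm) overrides auto-detection and
#' keeps results deterministic.
#'
#' @param mesh A height-field `surface_mesh` from [reconstruct_surface()].
#' @param rim_polygon Optional explicit rim polygon in the (x, y) plane.
#' @param depth_threshold Depth below the reference plane (mm) that flags
#'   wound nodes in auto-detection (default 0.1).
#' @return An object of class `wound_model`: `bed` and `cap`
#'   (`surface_mesh`es on the shared footprint triangulation), `rim`
#'   (ordered closed k x 3 loop), `volume_mm3`, `footprint_area_mm2`.
#' @export
extract_wound <- function(mesh, rim_polygon = NULL, depth_threshold = 0.1) {
  stopifnot(inherits(mesh, "surface_mesh"))
  g <- mesh$grid
  if (is.null(g)) stop("extract_wound needs a height-field mesh; run reconstruct_surface() first")
  Z <- g$Z; nx <- length(g$xs); ny <- length(g$ys)

  inside <- matrix(FALSE, ny, nx)
  if (is.null(rim_polygon)) {
    # reference plane from outer-boundary nodes of the defined region
    bnd <- boundary_nodes(Z)
    if (sum(bnd) < 3) stop("rim-detection error: too few boundary nodes")
    bxy <- node_coords(g, which(bnd))
    pl <- fit_plane(bxy)
    if (abs(pl$normal[3]) < 1e-6) stop("rim-detection error: vertical reference plane")
    ref_z <- (pl$d - pl$normal[1] * node_x(g) - pl$normal[2] * node_y(g)) / pl$normal[3]
    depth <- matrix(ref_z, ny, nx) - Z
    cand <- !is.na(Z) & depth > depth_threshold & !bnd
    if (!any(cand)) stop("rim-detection error: no closed rim found (no depressed region)")
    inside <- largest_component(cand)
  } else {
    rim_polygon <- as.matrix(rim_polygon)
    stopifnot(ncol(rim_polygon) == 2, nrow(rim_polygon) >= 3)
    pip <- point_in_polygon(node_x(g), node_y(g), rim_polygon)
    inside <- matrix(pip, ny, nx) & !is.na(Z)
    if (!any(inside)) stop("rim-detection error: rim polygon contains no grid nodes")
  }

  # rim ring: defined nodes 4-adjacent to the footprint but outside it
  ring <- matrix(FALSE, ny, nx)
  sh <- function(M, di, dj) {
    out <- matrix(FALSE, ny, nx)
    si <- max(1, 1 + di):min(ny, ny + di)
    sj <- max(1, 1 + dj):min(nx, nx + dj)
    out[si, sj] <- M[si - di, sj - dj]
    out
  }
  nb <- sh(inside, 1, 0) | sh(inside, -1, 0) | sh(inside, 0, 1) | sh(inside, 0, -1)
  ring <- nb & !inside & !is.na(Z)
  if (!any(ring)) stop("rim-detection error: wound region touches the scan border; no closed rim")

  foot <- inside | ring
  # harmonic cap: unknowns at interior nodes, Dirichlet data on the ring
  capZ <- Z
  un <- which(inside)
  if (length(un)) {
    unk_id <- matrix(NA_integer_, ny, nx)
    unk_id[un] <- seq_along(un)
    trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
    rhs <- numeric(length(un))
    ii <- ((un - 1L) %% ny) + 1L
    jj <- ((un - 1L) %/% ny) + 1L
    for (k in seq_along(un)) {
      i <- ii[k]; j <- jj[k]
      deg <- 0
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        i2 <- i + d[1]; j2 <- j + d[2]
        if (i2 < 1 || i2 > ny || j2 < 1 || j2 > nx) next
        if (inside[i2, j2]) {
          deg <- deg + 1
          trip_i <- c(trip_i, k); trip_j <- c(trip_j, unk_id[i2, j2])
          trip_x <- c(trip_x, -1)
        } else if (foot[i2, j2] || !is.na(Z[i2, j2])) {
          deg <- deg + 1
          rhs[k] <- rhs[k] + Z[i2, j2]
        }
      }
      trip_i <- c(trip_i, k); trip_j <- c(trip_j, k); trip_x <- c(trip_x, deg)
    }
    L <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                              dims = c(length(un), length(un)))
    capZ[un] <- as.numeric(Matrix::solve(L, rhs))
  }

  bedZ <- Z
  bedZ[!foot] <- NA
  capZ2 <- capZ
  capZ2[!foot] <- NA
  bed <- build_grid_mesh(g$xs, g$ys, bedZ, g$orient)
  cap <- build_grid_mesh(g$xs, g$ys, capZ2, g$orient)

  rim <- order_rim(g, ring)
  model <- structure(list(bed = bed, cap = cap, rim = rim,
                          inside = inside, ring = ring, grid = g),
                     class = "wound_model")
  model$volume_mm3 <- wound_volume(model)
  model$footprint_area_mm2 <- sum(!is.na(bedZ)) * g$step^2
  model
}

#' @export
print.wound_model <- function(x, ...) {
  cat(sprintf("<wound_model> volume %.3f mm^3, rim of %d vertices, footprint ~%.1f mm^2\n",
              x$volume_mm3, nrow(x$rim), x$footprint_area_mm2))
  invisible(x)
}

#' Defect volume between cap and bed
#'
#' Prismatic integration over the footprint triangulation shared by bed and
#' cap: for every triangle, (x, y) area times the mean of the three vertex
#' depths (cap z minus bed z).
#'
#' @param model A `wound_model`.
#' @return Volume in mm^3.
#' @export
wound_volume <- function(model) {
  stopifnot(inherits(model, "wound_model"))
  bed <- model$bed; cap <- model$cap
  if (nrow(bed$faces) != nrow(cap$faces)) stop("topology error: cap/bed triangulations differ")
  if (nrow(bed$faces) == 0) return(0)
  Vb <- bed$vertices; Vc <- cap$vertices
  F <- bed$faces
  depth <- Vc[, 3] - Vb[, 3]
  e1 <- Vb[F[, 2], 1:2, drop = FALSE] - Vb[F[, 1], 1:2, drop = FALSE]
  e2 <- Vb[F[, 3], 1:2, drop = FALSE] - Vb[F[, 1], 1:2, drop = FALSE]
  area_xy <- 0.5 * abs(e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  dmean <- (depth[F[, 1]] + depth[F[, 2]] + depth[F[, 3]]) / 3
  sum(area_xy * dmean)
}

#' Save a wound model as a directory bundle
#'
#' Writes `bed.ply`, `cap.ply`, `rim.json` and `summary.json` (volume,
#' footprint area, rim length) into `dir`.
#'
#' @param model A `wound_model`.
#' @param dir Output directory (created if missing).
#' @export
save_wound_model <- function(model, dir) {
  stopifnot(inherits(model, "wound_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  save_mesh(model$bed, file.path(dir, "bed.ply"))
  save_mesh(model$cap, file.path(dir, "cap.ply"))
  jsonlite::write_json(list(units = "mm", rim = model$rim),
                       file.path(dir, "rim.json"), digits = NA)
  jsonlite::write_json(list(volume_mm3 = model$volume_mm3,
                            footprint_area_mm2 = model$footprint_area_mm2,
                            rim_vertices = nrow(model$rim)),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# ---- grid helpers --------------------------------------------------------

node_x <- function(g) rep(g$xs, each = length(g$ys))
node_y <- function(g) rep(g$ys, times = length(g$xs))

node_coords <- function(g, lin) {
  ny <- length(g$ys)
  i <- ((lin - 1L) %% ny) + 1L
  j <- ((lin - 1L) %/% ny) + 1L
  cbind(g$xs[j], g$ys[i], g$Z[lin])
}

# defined nodes on the outer edge of the defined region
boundary_nodes <- function(Z) {
  ny <- nrow(Z); nx <- ncol(Z)
  def <- !is.na(Z)
  out <- matrix(FALSE, ny, nx)
  for (j in seq_len(nx)) {
    for (i in seq_len(ny)) {
      if (!def[i, j]) next
      if (i == 1 || i == ny || j == 1 || j == nx ||
          !def[i - 1, j] || !def[i + 1, j] || !def[i, j - 1] || !def[i, j + 1]) {
        out[i, j] <- TRUE
      }
    }
  }
  out
}

# largest 4-connected component of a logical matrix
largest_component <- function(M) {
  ny <- nrow(M); nx <- ncol(M)
  lab <- matrix(0L, ny, nx)
  cur <- 0L
  sizes <- integer(0)
  for (start in which(M)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    n <- 0L
    while (length(queue)) {
      v <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      n <- n + 1L
      i <- ((v - 1L) %% ny) + 1L
      j <- ((v - 1L) %/% ny) + 1L
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        i2 <- i + d[1]; j2 <- j + d[2]
        if (i2 >= 1 && i2 <= ny && j2 >= 1 && j2 <= nx) {
          v2 <- (j2 - 1L) * ny + i2
          if (M[v2] && lab[v2] == 0L) {
            lab[v2] <- cur
            queue <- c(queue, v2)
          }
        }
      }
    }
    sizes[cur] <- n
  }
  if (!cur) return(M & FALSE)
  lab == which.max(sizes)
}

# order rim ring nodes into a closed loop (angular order around centroid)
order_rim <- function(g, ring) {
  lin <- which(ring)
  xyz <- node_coords(g, lin)
  cx <- mean(xyz[, 1]); cy <- mean(xyz[, 2])
  ang <- atan2(xyz[, 2] - cy, xyz[, 1] - cx)
  xyz <- xyz[order(ang), , drop = FALSE]
  rbind(xyz, xyz[1, , drop = FALSE])
}

# ray-crossing point-in-polygon, vectorized over query points
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi + (yj == yi) * 1e-300) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Sample height and normal of a height-field mesh at (x, y) points
#'
#' Projects points along the z axis onto the mesh: locates the containing
#' triangle (fast grid lookup when metadata is present, face search
#' otherwise) and barycentrically interpolates vertex positions and vertex
#' normals.
#'
#' @param mesh A `surface_mesh`.
#' @param xy k x 2 matrix of query points (mm).
#' @return A list with `points` (k x 3, on the mesh) and `normals` (k x 3,
#'   unit). Queries outside the mesh footprint raise a coverage error
#'   listing the offending rows.
#' @export
surface_sample <- function(mesh, xy) {
  stopifnot(inherits(mesh, "surface_mesh"))
  xy <- matrix(as.numeric(xy), ncol = 2)
  V <- mesh$vertices
  N <- if (!is.null(mesh$normals)) mesh$normals else vertex_normals(V, mesh$faces)
  k <- nrow(xy)
  P <- matrix(NA_real_, k, 3)
  NN <- matrix(NA_real_, k, 3)
  g <- mesh$grid
  bad <- integer(0)
  if (!is.null(g)) {
    ny <- length(g$ys)
    for (q in seq_len(k)) {
      x <- xy[q, 1]; y <- xy[q, 2]
      j <- findInterval(x, g$xs); i <- findInterval(y, g$ys)
      hit <- FALSE
      for (jj in unique(pmax(1, pmin(length(g$xs) - 1, c(j - 1, j))))) {
        for (ii in unique(pmax(1, pmin(ny - 1, c(i - 1, i))))) {
          a <- g$idx[ii, jj]; b <- g$idx[ii, jj + 1]
          cc <- g$idx[ii + 1, jj + 1]; d <- g$idx[ii + 1, jj]
          for (tri in list(c(a, b, cc), c(a, cc, d))) {
            if (any(is.na(tri))) next
            w <- bary2d(V[tri, 1:2, drop = FALSE], c(x, y))
            if (!is.null(w)) {
              P[q, ] <- w %*% V[tri, , drop = FALSE]
              nn <- w %*% N[tri, , drop = FALSE]
              NN[q, ] <- nn / sqrt(sum(nn^2))
              hit <- TRUE
              break
            }
          }
          if (hit) break
        }
        if (hit) break
      }
      if (!hit) bad <- c(bad, q)
    }
  } else {
    F <- mesh$faces
    for (q in seq_len(k)) {
      x <- xy[q, 1]; y <- xy[q, 2]
      hit <- FALSE
      for (f in seq_len(nrow(F))) {
        tri <- F[f, ]
        w <- bary2d(V[tri, 1:2, drop = FALSE], c(x, y))
        if (!is.null(w)) {
          P[q, ] <- w %*% V[tri, , drop = FALSE]
          nn <- w %*% N[tri, , drop = FALSE]
          NN[q, ] <- nn / sqrt(sum(nn^2))
          hit <- TRUE
          break
        }
      }
      if (!hit) bad <- c(bad, q)
    }
  }
  if (length(bad)) {
    stop("coverage error: samples outside mesh footprint at rows ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "")
  }
  list(points = P, normals = NN)
}

# 2D barycentric weights of point pt in triangle T (3 x 2); NULL if outside
bary2d <- function(T, pt, tol = 1e-9) {
  d <- (T[2, 2] - T[3, 2]) * (T[1, 1] - T[3, 1]) +
    (T[3, 1] - T[2, 1]) * (T[1, 2] - T[3, 2])
  if (abs(d) < 1e-300) return(NULL)
  w1 <- ((T[2, 2] - T[3, 2]) * (pt[1] - T[3, 1]) +
           (T[3, 1] - T[2, 1]) * (pt[2] - T[3, 2])) / d
  w2 <- ((T[3, 2] - T[1, 2]) * (pt[1] - T[3, 1]) +
           (T[1, 1] - T[3, 1]) * (pt[2] - T[3, 2])) / d
  w3 <- 1 - w1 - w2
  if (w1 < -tol || w2 < -tol || w3 < -tol) return(NULL)
  c(w1, w2, w3)
}
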