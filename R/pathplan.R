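# Printing-plan generation: planar serpentine rasters, conformal projection
# onto the wound surface, volume-exact bioink allocation, print strategy
# selection and the printable-angle model.
#
# Waypoint orientation convention: the six coordinates of a waypoint are the
# position plus the Euler angles (intrinsic Z-Y-X) of the *local surface
# frame* — z along the outward surface normal, x along the travel direction.
# The print head approaches along -z of that frame, i.e. the tool +z axis is
# anti-parallel to the surface normal; on a flat horizontal surface pitch
# and roll are zero.

#' Toolpath container
#'
#' A tibble of ordered six-coordinate waypoints: `x`, `y`, `z` (mm), `yaw`,
#' `pitch`, `roll` (rad), `extrude` (microlitres deposited on the segment
#' ending at the waypoint) and `layer`. Strategy and planning parameters
#' ride along as attributes (`strategy`, `total_volume_ul`, `line_spacing`,
#' `layer_height`).
#'
#' @param df Data frame with the waypoint columns.
#' @param strategy `"conformal"` or `"point_to_point"`.
#' @param total_volume_ul Total bioink volume (microlitres).
#' @param line_spacing,layer_height Planning parameters (mm).
#' @return A `toolpath` tibble.
#' @export
toolpath <- function(df, strategy = c("conformal", "point_to_point"),
                     total_volume_ul = 0, line_spacing = NA_real_,
                     layer_height = NA_real_) {
  strategy <- match.arg(strategy)
  df <- tibble::as_tibble(df)
  need <- c("x", "y", "z", "yaw", "pitch", "roll", "extrude", "layer")
  stopifnot(all(need %in% names(df)), all(df$extrude >= 0))
  structure(df, class = c("toolpath", class(tibble::tibble())),
            strategy = strategy, total_volume_ul = total_volume_ul,
            line_spacing = line_spacing, layer_height = layer_height)
}

#' @export
print.toolpath <- function(x, ...) {
  cat(sprintf("<toolpath> %s, %d waypoints, %d layer(s), %.3f ul total\n",
              attr(x, "strategy"), nrow(x), length(unique(x$layer)),
              sum(x$extrude)))
  NextMethod()
}

#' Serpentine (boustrophedon) raster over a polygon
#'
#' Horizontal scan lines at `line_spacing` pitch are clipped to the polygon
#' and connected in alternating direction, covering the interior the way a
#' planar slicer fills a region.
#'
#' @param footprint Simple polygon, k x 2 matrix (mm), open or closed.
#' @param line_spacing Scan-line pitch, mm, > 0.
#' @return A tibble of ordered path vertices: `x`, `y`, `scanline`.
#' @export
plan_planar_raster <- function(footprint, line_spacing) {
  footprint <- as.matrix(footprint)
  stopifnot(ncol(footprint) == 2, line_spacing > 0)
  if (nrow(footprint) >= 2 &&
      all(footprint[1, ] == footprint[nrow(footprint), ])) {
    footprint <- footprint[-nrow(footprint), , drop = FALSE]
  }
  if (nrow(footprint) < 3) stop("degenerate polygon: fewer than 3 vertices")
  xs <- footprint[, 1]; ys <- footprint[, 2]
  area <- abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
  if (area < 1e-9) stop("degenerate polygon: zero area")

  ylo <- min(ys); yhi <- max(ys)
  lines_y <- seq(ylo, yhi, by = line_spacing)
  eps <- (yhi - ylo) * 1e-9
  lines_y[1] <- lines_y[1] + eps
  if (length(lines_y) > 1 && abs(lines_y[length(lines_y)] - yhi) < eps) {
    lines_y[length(lines_y)] <- yhi - eps
  }

  n <- nrow(footprint)
  rows <- list()
  for (li in seq_along(lines_y)) {
    y <- lines_y[li]
    xhits <- numeric(0)
    j <- n
    for (i in seq_len(n)) {
      yi <- ys[i]; yj <- ys[j]
      if ((yi > y) != (yj > y)) {
        xhits <- c(xhits, xs[i] + (y - yi) / (yj - yi) * (xs[j] - xs[i]))
      }
      j <- i
    }
    xhits <- sort(xhits)
    if (length(xhits) >= 2) {
      # pair up crossings into inside intervals
      iv <- matrix(xhits[seq_len(2 * (length(xhits) %/% 2))], ncol = 2, byrow = TRUE)
      if (li %% 2 == 0) iv <- iv[rev(seq_len(nrow(iv))), c(2, 1), drop = FALSE]
      for (r in seq_len(nrow(iv))) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          x = c(iv[r, 1], iv[r, 2]), y = y, scanline = li)
      }
    }
  }
  if (!length(rows)) stop("degenerate polygon: no scan line intersections")
  dplyr::bind_rows(rows)
}

#' Project a planar path conformally onto a surface
#'
#' Resamples the 2D path at `step` arc length, drops each sample along the
#' projection axis (z) onto the mesh, and attaches the interpolated surface
#' frame at each waypoint: z along the outward surface normal, x along
#' travel. On a flat horizontal mesh the result equals the planar path with
#' zero pitch and roll.
#'
#' @param path2d Tibble or matrix with `x`, `y` columns (ordered polyline).
#' @param mesh A `surface_mesh` covering the path footprint.
#' @param step Resampling arc-length step, mm.
#' @return A [toolpath()] (extrusion zeroed; see [allocate_bioink()]).
#' @export
project_conformal <- function(path2d, mesh, step = 0.5) {
  if (is.data.frame(path2d)) path2d <- cbind(path2d$x, path2d$y)
  path2d <- matrix(as.numeric(path2d), ncol = 2)
  stopifnot(nrow(path2d) >= 2, step > 0)
  xy <- resample_polyline(path2d, step)
  s <- surface_sample(mesh, xy)
  P <- s$points; N <- s$normals
  k <- nrow(P)
  yaw <- pitch <- roll <- numeric(k)
  for (i in seq_len(k)) {
    t2d <- if (i < k) xy[min(i + 1, k), ] - xy[i, ] else xy[i, ] - xy[max(i - 1, 1), ]
    R <- frame_from_normal(N[i, ], c(t2d, 0))
    e <- rotation_to_euler(R)
    yaw[i] <- e$yaw; pitch[i] <- e$pitch; roll[i] <- e$roll
  }
  toolpath(tibble::tibble(x = P[, 1], y = P[, 2], z = P[, 3],
                          yaw = yaw, pitch = pitch, roll = roll,
                          extrude = 0, layer = 0L),
           strategy = "conformal", total_volume_ul = 0,
           line_spacing = NA_real_, layer_height = NA_real_)
}

# right-handed frame with z = n (unit) and x close to the hint direction
frame_from_normal <- function(n, x_hint) {
  z <- n / sqrt(sum(n^2))
  x <- x_hint - sum(x_hint * z) * z
  if (sqrt(sum(x^2)) < 1e-12) {
    x <- c(1, 0, 0) - z[1] * z
    if (sqrt(sum(x^2)) < 1e-12) x <- c(0, 1, 0) - z[2] * z
  }
  x <- x / sqrt(sum(x^2))
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  cbind(x, y, z)
}

# resample an ordered polyline at fixed arc-length step (keeps endpoints)
resample_polyline <- function(pts, step) {
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  cs <- c(0, cumsum(seg))
  L <- cs[length(cs)]
  if (L == 0) return(pts[1, , drop = FALSE])
  tgt <- unique(c(seq(0, L, by = step), L))
  out <- matrix(NA_real_, length(tgt), ncol(pts))
  for (q in seq_along(tgt)) {
    t <- tgt[q]
    i <- findInterval(t, cs, rightmost.closed = TRUE)
    i <- min(max(i, 1), length(seg))
    f <- if (seg[i] > 0) (t - cs[i]) / seg[i] else 0
    out[q, ] <- pts[i, ] + f * (pts[i + 1, ] - pts[i, ])
  }
  out
}

#' Allocate bioink volume over a toolpath
#'
#' Conservation is exact: the per-waypoint extrusions sum to
#' `total_volume_ul`. Conformal paths split the volume proportionally to
#' segment arc length (within each layer, using the layer's volume share);
#' point-to-point paths split by the `weights` argument (equal by default).
#'
#' @param path A [toolpath()].
#' @param total_volume_ul Total volume, microlitres, >= 0.
#' @param weights Optional per-point weights (point_to_point only).
#' @param layer_volumes Optional per-layer volumes (conformal, multi-layer);
#'   must sum to `total_volume_ul`.
#' @return The toolpath with `extrude` filled.
#' @export
allocate_bioink <- function(path, total_volume_ul, weights = NULL,
                            layer_volumes = NULL) {
  stopifnot(inherits(path, "toolpath"), total_volume_ul >= 0)
  if (nrow(path) == 0) {
    if (total_volume_ul > 0) stop("empty path cannot carry positive volume")
    return(path)
  }
  strategy <- attr(path, "strategy")
  ex <- numeric(nrow(path))
  if (total_volume_ul > 0) {
    if (strategy == "point_to_point") {
      w <- if (is.null(weights)) rep(1, nrow(path)) else as.numeric(weights)
      stopifnot(length(w) == nrow(path), all(w >= 0), sum(w) > 0)
      ex <- total_volume_ul * w / sum(w)
      ex[length(ex)] <- total_volume_ul - sum(ex[-length(ex)])
    } else {
      layers <- sort(unique(path$layer))
      lv <- if (is.null(layer_volumes)) {
        # split across layers by their path length
        len_by_layer <- vapply(layers, function(l) {
          polyline_length(path[path$layer == l, c("x", "y", "z")])
        }, numeric(1))
        if (sum(len_by_layer) == 0) stop("degenerate toolpath: zero length")
        total_volume_ul * len_by_layer / sum(len_by_layer)
      } else {
        stopifnot(length(layer_volumes) == length(layers))
        if (abs(sum(layer_volumes) - total_volume_ul) > 1e-9 * max(1, total_volume_ul)) {
          stop("layer_volumes must sum to total_volume_ul")
        }
        as.numeric(layer_volumes)
      }
      for (li in seq_along(layers)) {
        sel <- which(path$layer == layers[li])
        pts <- as.matrix(path[sel, c("x", "y", "z")])
        seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                               pts[-nrow(pts), , drop = FALSE])^2))
        if (length(seg) == 0 || sum(seg) == 0) {
          ex[sel[length(sel)]] <- lv[li]
          next
        }
        e <- lv[li] * seg / sum(seg)
        e[length(e)] <- lv[li] - sum(e[-length(e)])
        ex[sel[-1]] <- e
      }
      # exact global conservation
      nz <- which(ex > 0)
      if (length(nz)) ex[nz[length(nz)]] <- ex[nz[length(nz)]] +
          (total_volume_ul - sum(ex))
    }
  }
  path$extrude <- ex
  attr(path, "total_volume_ul") <- total_volume_ul
  path
}

polyline_length <- function(df) {
  pts <- as.matrix(df)
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2)))
}

#' Choose the printing strategy for a wound
#'
#' Small defects are filled by direct point-to-point bioink delivery in
#' strict accordance with the wound volume; larger defects get a planar
#' raster projected into a conformal toolpath. The volume threshold defaults
#' to 20 mm^3, which sends 2- and 5-mm biopsy-punch wounds to point mode and
#' a 10-mm wound (about 31 mm^3) to conformal mode. Ties go to conformal.
#'
#' @param model A `wound_model` or a volume in mm^3.
#' @param threshold_volume Threshold, mm^3 (default 20).
#' @return `"point_to_point"` or `"conformal"`.
#' @export
choose_strategy <- function(model, threshold_volume = 20) {
  v <- if (inherits(model, "wound_model")) model$volume_mm3 else as.numeric(model)
  stopifnot(is.finite(v), v >= 0, threshold_volume > 0)
  if (v < threshold_volume) "point_to_point" else "conformal"
}

#' Printability (thread-skid) model
#'
#' Extruded hydrogel threads adhere to an inclined plane only up to a
#' critical inclination: beyond the skid threshold (70 degrees for the
#' reference hydrogel) threads roll or slide. A fixed-vertical print head
#' can therefore print only inclinations within the threshold either side
#' of vertical; a head that aligns with the local surface normal sees zero
#' relative inclination everywhere and the skid condition never triggers.
#'
#' @param skid_threshold Critical inclination, degrees, in (0, 90].
#' @param mode `"fixed_vertical"` or `"normal_aligned"`.
#' @return A list of class `printability_model`.
#' @export
printability_model <- function(skid_threshold = 70,
                               mode = c("fixed_vertical", "normal_aligned")) {
  mode <- match.arg(mode)
  stopifnot(skid_threshold > 0, skid_threshold <= 90)
  structure(list(skid_threshold = skid_threshold, mode = mode),
            class = "printability_model")
}

#' Printable angular range of a print-head configuration
#'
#' @param model A [printability_model()].
#' @return Printable range in degrees: `2 * skid_threshold` (symmetric about
#'   vertical) for a fixed-vertical head, 360 for a normal-aligned head.
#' @examples
#' printable_range(printability_model(70, "fixed_vertical"))  # 140
#' printable_range(printability_model(mode = "normal_aligned"))  # 360
#' @export
printable_range <- function(model) {
  stopifnot(inherits(model, "printability_model"))
  switch(model$mode,
         fixed_vertical = 2 * model$skid_threshold,
         normal_aligned = 360)
}

#' Plan a full printing job for a wound
#'
#' Selects the strategy by defect volume, builds the path (conformal
#' multi-layer raster over the wound bed, or a point grid for small
#' defects), and allocates bioink so the deposited volume equals the defect
#' volume (1 mm^3 = 1 microlitre, incompressible bioink). Conformal layers
#' are repeated offsets of the bed path along the projection axis at
#' `layer_height` until the cumulative layer volume reaches the defect
#' volume; the last layer's share is scaled down to conserve volume.
#'
#' @param model A `wound_model`.
#' @param line_spacing Raster pitch, mm.
#' @param step Waypoint arc-length step, mm.
#' @param layer_height Conformal layer height, mm.
#' @param threshold_volume Strategy threshold, mm^3.
#' @param point_pitch Point-grid pitch for point_to_point mode, mm.
#' @return A [toolpath()].
#' @export
plan_wound <- function(model, line_spacing = 1.0, step = 0.5,
                       layer_height = 0.5, threshold_volume = 20,
                       point_pitch = 1.0) {
  stopifnot(inherits(model, "wound_model"))
  strategy <- choose_strategy(model, threshold_volume)
  vol <- model$volume_mm3
  if (strategy == "point_to_point") {
    g <- model$grid
    lin <- which(model$inside)
    xyz <- node_coords(g, lin)
    keep <- seq(1, nrow(xyz), by = max(1L, round(point_pitch / g$step)))
    xyz <- xyz[keep, , drop = FALSE]
    tp <- toolpath(tibble::tibble(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                                  yaw = 0, pitch = 0, roll = 0,
                                  extrude = 0, layer = 0L),
                   strategy = "point_to_point",
                   line_spacing = NA_real_, layer_height = NA_real_)
    return(allocate_bioink(tp, vol))
  }
  # inset the rim toward its centroid so every raster sample lies strictly
  # inside the bed triangulation
  rim_xy <- model$rim[, 1:2, drop = FALSE]
  ctr <- colMeans(rim_xy)
  inset <- 1.5 * model$grid$step
  rim_in <- t(apply(rim_xy, 1, function(v) {
    d <- v - ctr
    len <- sqrt(sum(d^2))
    ctr + d * max(0, (len - inset)) / max(len, 1e-12)
  }))
  raster <- plan_planar_raster(rim_in, line_spacing)
  base <- project_conformal(raster, model$bed, step = step)
  area <- model$footprint_area_mm2
  n_layers <- max(1L, ceiling(vol / (area * layer_height)))
  layers <- vector("list", n_layers)
  lv <- numeric(n_layers)
  for (k in seq_len(n_layers)) {
    lk <- base
    lk$z <- lk$z + (k - 1) * layer_height
    lk$layer <- k - 1L
    layers[[k]] <- tibble::as_tibble(lk)
    lv[k] <- if (k < n_layers) area * layer_height else
      vol - (n_layers - 1) * area * layer_height
  }
  tp <- toolpath(dplyr::bind_rows(layers), strategy = "conformal",
                 line_spacing = line_spacing, layer_height = layer_height)
  allocate_bioink(tp, vol, layer_volumes = lv)
}

#' Export a toolpath as JSON or a 6-axis G-code-like dialect
#'
#' The text dialect writes one `G1 X Y Z A B C E` line per waypoint: X/Y/Z
#' in mm, A/B/C the yaw/pitch/roll of the surface frame in degrees (angles
#' leave the package in degrees only at file boundaries), E the cumulative
#' extruded volume in microlitres. Header comments document units and
#' conventions.
#'
#' @param path A [toolpath()].
#' @param file Output file.
#' @export
write_toolpath_json <- function(path, file) {
  stopifnot(inherits(path, "toolpath"))
  obj <- list(
    convention = list(units = "mm, rad, ul",
                      euler = "intrinsic Z-Y-X yaw-pitch-roll of the surface frame",
                      tool = "print head approaches along -z of the surface frame"),
    strategy = attr(path, "strategy"),
    total_volume_ul = attr(path, "total_volume_ul"),
    line_spacing = attr(path, "line_spacing"),
    layer_height = attr(path, "layer_height"),
    waypoints = tibble::as_tibble(path)
  )
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(file)
}

#' @rdname write_toolpath_json
#' @export
write_toolpath_gcode <- function(path, file) {
  stopifnot(inherits(path, "toolpath"))
  deg <- 180 / pi
  hdr <- c("; woundpath 6-axis dialect",
           "; X Y Z in mm; A=yaw B=pitch C=roll in degrees (intrinsic Z-Y-X surface frame)",
           "; E cumulative extruded volume in microlitres",
           sprintf("; strategy=%s layers=%d", attr(path, "strategy"),
                   length(unique(path$layer))))
  E <- cumsum(path$extrude)
  lines <- sprintf("G1 X%.4f Y%.4f Z%.4f A%.4f B%.4f C%.4f E%.5f",
                   path$x, path$y, path$z,
                   path$yaw * deg, path$pitch * deg, path$roll * deg, E)
  writeLines(c(hdr, lines), file)
  invisible(file)
}
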