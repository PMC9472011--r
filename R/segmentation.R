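# Colour-filter wound segmentation.
#
# Images are numeric arrays [row, col, channel] with values in [0, 1]
# (the layout of png::readPNG). Pixel convention: (u, v) = (column, row),
# origin at the top-left pixel centre, 0-based: u = col - 1, v = row - 1.
#
# Pipeline (in order): linear normalization -> RGB-to-HSV colour filter ->
# Gaussian blur (sigma 0.5 px) -> image-gradient thresholding to remove
# unwanted margins -> morphological erosion -> contour + barycentre
# extraction. Blur, erosion, labelling and ordered contours are delegated
# to EBImage.

#' Segmentation configuration
#'
#' Wounds are segmented by an HSV colour filter: their colour differs
#' markedly from surrounding skin, so a hue/saturation/value band isolates
#' them. Hue is in degrees `[0, 360)`; a band with `hue_min > hue_max` wraps
#' through 0 (red). Saturation and value are in `[0, 1]`.
#'
#' The defaults target the synthetic fixture palette (deep-red wound on a
#' skin-toned background); real imagery needs recalibrated bands.
#'
#' @param hue_min,hue_max Hue band, degrees.
#' @param sat_min,sat_max Saturation band.
#' @param val_min,val_max Value (brightness) band.
#' @param gaussian_sigma Denoising blur standard deviation, px (default 0.5).
#' @param gradient_threshold Sobel-magnitude threshold above which margin
#'   pixels are removed after blurring.
#' @param erosion_radius Disc radius (px) of the final morphological erosion.
#' @param min_area Components below this area (px^2) are dropped.
#' @param drop_border_components Remove components touching the image border
#'   (unwanted margins).
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(hue_min = 335, hue_max = 15,
                                sat_min = 0.35, sat_max = 1,
                                val_min = 0.10, val_max = 1,
                                gaussian_sigma = 0.5,
                                gradient_threshold = 2.0,
                                erosion_radius = 1L,
                                min_area = 20,
                                drop_border_components = TRUE) {
  stopifnot(gaussian_sigma > 0, erosion_radius >= 0, min_area >= 0,
            hue_min >= 0, hue_min < 360, hue_max >= 0, hue_max < 360,
            sat_min >= 0, sat_max <= 1, val_min >= 0, val_max <= 1)
  structure(list(hue_min = hue_min, hue_max = hue_max,
                 sat_min = sat_min, sat_max = sat_max,
                 val_min = val_min, val_max = val_max,
                 gaussian_sigma = gaussian_sigma,
                 gradient_threshold = gradient_threshold,
                 erosion_radius = as.integer(erosion_radius),
                 min_area = min_area,
                 drop_border_components = drop_border_components),
            class = "segmentation_config")
}

#' Linear per-channel normalization
#'
#' Min-max rescales each channel to `[0, 1]`, removing global glare/shadow
#' offsets so downstream colour filtering is invariant to affine brightness
#' changes. A constant channel maps to 0.
#'
#' @param img Numeric array `[row, col, 3]` (or a 2D matrix).
#' @return Array of the same shape with each channel spanning `[0, 1]`.
#' @export
normalize_image <- function(img) {
  if (length(img) == 0) stop("empty image")
  if (is.matrix(img)) img <- array(img, c(dim(img), 1))
  stopifnot(length(dim(img)) == 3)
  out <- img
  for (k in seq_len(dim(img)[3])) {
    ch <- img[, , k]
    rng <- range(ch)
    out[, , k] <- if (rng[2] > rng[1]) (ch - rng[1]) / (rng[2] - rng[1]) else 0
  }
  if (dim(out)[3] == 1) out[, , 1] else out
}

# HSV mask of an RGB array; hue band may wrap through 0
hsv_mask <- function(img, cfg) {
  d <- dim(img)
  rgb <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  h <- hsv[1, ] * 360
  s <- hsv[2, ]
  v <- hsv[3, ]
  in_h <- if (cfg$hue_min <= cfg$hue_max) {
    h >= cfg$hue_min & h <= cfg$hue_max
  } else {
    h >= cfg$hue_min | h <= cfg$hue_max
  }
  m <- in_h & s >= cfg$sat_min & s <= cfg$sat_max &
    v >= cfg$val_min & v <= cfg$val_max
  matrix(as.numeric(m), d[1], d[2])
}

# Sobel gradient magnitude of a matrix (zero-padded borders)
sobel_magnitude <- function(m) {
  pad <- rbind(0, cbind(0, m, 0), 0)
  nr <- nrow(m); nc <- ncol(m)
  sh <- function(dr, dc) pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  gx <- sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1) -
    (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  gy <- sh(1, -1) + 2 * sh(1, 0) + sh(1, 1) -
    (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  sqrt(gx^2 + gy^2)
}

#' Segment wound regions from an RGB image
#'
#' Runs the full colour-filter pipeline and returns one contour per
#' connected wound region, sorted by area (descending). An image with no
#' in-band pixels yields an empty list, not an error.
#'
#' @param img Numeric RGB array `[row, col, 3]` in `[0, 1]`.
#' @param cfg A [segmentation_config()].
#' @return A list of `wound_contour` objects, each with `polygon` (closed
#'   (u, v) pixel polygon, 0-based), `centroid` (area barycentre of the
#'   filled region, px) and `area` (px^2).
#' @export
segment_wound <- function(img, cfg = segmentation_config()) {
  stopifnot(inherits(cfg, "segmentation_config"),
            length(dim(img)) == 3, dim(img)[3] >= 3)
  img <- normalize_image(img)
  mask <- hsv_mask(img, cfg)
  # EBImage works on (x, y) = (col, row) layout
  mb <- EBImage::gblur(EBImage::Image(t(mask)), sigma = cfg$gaussian_sigma,
                       radius = max(3, 2 * ceiling(3 * cfg$gaussian_sigma) + 1))
  mb <- t(EBImage::imageData(mb))
  grad <- sobel_magnitude(mb)
  bin <- (mb > 0.5) & !(grad > cfg$gradient_threshold)
  if (cfg$erosion_radius > 0) {
    brush <- EBImage::makeBrush(2L * cfg$erosion_radius + 1L, shape = "disc")
    er <- EBImage::erode(EBImage::Image(t(bin * 1)), brush)
    bin <- t(EBImage::imageData(er)) > 0.5
  }
  if (!any(bin)) return(list())
  lab <- EBImage::bwlabel(EBImage::Image(t(bin * 1)))
  labm <- t(EBImage::imageData(lab))
  ids <- sort(setdiff(unique(as.vector(labm)), 0))
  if (cfg$drop_border_components && length(ids)) {
    border <- unique(c(labm[1, ], labm[nrow(labm), ], labm[, 1], labm[, ncol(labm)]))
    ids <- setdiff(ids, border)
  }
  contours <- EBImage::ocontour(lab)
  out <- list()
  for (id in ids) {
    px <- which(labm == id, arr.ind = TRUE)  # (row, col) 1-based
    area <- nrow(px)
    if (area < cfg$min_area) next
    centroid <- c(u = mean(px[, 2]) - 1, v = mean(px[, 1]) - 1)
    poly <- contours[[id]]  # (x, y) 1-based in EBImage layout
    poly <- cbind(u = poly[, 1] - 1, v = poly[, 2] - 1)
    if (nrow(poly) > 1 && any(poly[1, ] != poly[nrow(poly), ])) {
      poly <- rbind(poly, poly[1, ])
    }
    out[[length(out) + 1]] <- structure(
      list(polygon = poly, centroid = centroid, area = area),
      class = "wound_contour")
  }
  out[order(vapply(out, function(ct) ct$area, numeric(1)), decreasing = TRUE)]
}

#' @export
print.wound_contour <- function(x, ...) {
  cat(sprintf("<wound_contour> area = %d px^2, centroid = (%.2f, %.2f) px\n",
              x$area, x$centroid[1], x$centroid[2]))
  invisible(x)
}

#' Tabulate segmented contours
#' @param contours Result of [segment_wound()].
#' @return A tibble with one row per contour: `id`, `u`, `v` (centroid, px),
#'   `area` (px^2).
#' @export
contours_table <- function(contours) {
  tibble::tibble(
    id = seq_along(contours),
    u = vapply(contours, function(ct) ct$centroid[[1]], numeric(1)),
    v = vapply(contours, function(ct) ct$centroid[[2]], numeric(1)),
    area = vapply(contours, function(ct) ct$area, numeric(1))
  )
}
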