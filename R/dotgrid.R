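# Static-recognition accuracy evaluation on the dot-grid target.

# intensity-weighted dark-blob centroids of a rendered grid image (0-based
# px). Blobs found by thresholding; the centroid integrates darkness over an
# expanded window around each blob so anti-aliased edge tails are included.
detect_dots <- function(img, value_threshold = 0.5, min_area = 4, pad = 4L) {
  v <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  dark <- v < value_threshold
  if (!any(dark)) return(matrix(numeric(0), 0, 2))
  lab <- EBImage::bwlabel(EBImage::Image(t(dark * 1)))
  labm <- t(EBImage::imageData(lab))
  ids <- setdiff(unique(as.vector(labm)), 0)
  out <- matrix(NA_real_, length(ids), 2)
  wmat <- 1 - v
  keep <- logical(length(ids))
  for (k in seq_along(ids)) {
    px <- which(labm == ids[k], arr.ind = TRUE)
    if (nrow(px) < min_area) next
    r0 <- max(1, min(px[, 1]) - pad); r1 <- min(nrow(v), max(px[, 1]) + pad)
    c0 <- max(1, min(px[, 2]) - pad); c1 <- min(ncol(v), max(px[, 2]) + pad)
    wb <- wmat[r0:r1, c0:c1]
    tot <- sum(wb)
    cu <- sum(rep(c0:c1 - 1, each = nrow(wb)) * wb) / tot
    cv <- sum(rep(r0:r1 - 1, times = ncol(wb)) * wb) / tot
    out[k, ] <- c(cu, cv)
    keep[k] <- TRUE
  }
  out[keep, , drop = FALSE]
}

#' Evaluate recognition accuracy on a rendered dot-grid pair
#'
#' Detects the dot centroids in both images (intensity-weighted dark-blob
#' centroids), pairs left/right detections through the projected truth
#' (pixel gate `px_gate`), triangulates each pair, and matches the
#' triangulated points to the true 3D dot centres by nearest neighbour with
#' a 10 mm gate (half the grid pitch, to avoid cross-dot mismatches). The
#' per-dot planar recognition error dP is the in-plane component (grid
#' plane z = 0) of the triangulated-minus-truth offset.
#'
#' Detection shortfalls (< expected dots) are reported in the result, not
#' raised as errors.
#'
#' @param rig The stereo rig that rendered the pair.
#' @param left,right RGB arrays of the rendered grid.
#' @param truth Tibble of true dot centres (`x`, `y`, `z`).
#' @param centroid_noise_px Optional Gaussian pixel noise added to each
#'   detected centroid (simulating detection noise); seeded.
#' @param seed Seed for `centroid_noise_px`.
#' @param gate_mm 3D match gate, mm (default 10 = half pitch).
#' @param px_gate Left/right pairing gate, px.
#' @return A list: `dots` (tibble with truth position, estimate, `dP_mm`,
#'   `err3d_mm`), `n_expected`, `n_detected_left/right`, `n_matched`,
#'   `shortfall`.
#' @export
evaluate_dot_grid <- function(rig, left, right, truth,
                              centroid_noise_px = 0, seed = 1L,
                              gate_mm = 10, px_gate = 12) {
  stopifnot(inherits(rig, "stereo_rig"))
  cl <- detect_dots(left)
  cr <- detect_dots(right)
  if (centroid_noise_px > 0) {
    noise <- withr::with_seed(as.integer(seed), {
      list(l = matrix(stats::rnorm(length(cl), 0, centroid_noise_px), nrow(cl), 2),
           r = matrix(stats::rnorm(length(cr), 0, centroid_noise_px), nrow(cr), 2))
    })
    cl <- cl + noise$l
    cr <- cr + noise$r
  }
  Xt <- as.matrix(truth[, c("x", "y", "z")])
  rows <- list()
  for (i in seq_len(nrow(Xt))) {
    uvl <- project(rig$left, Xt[i, ])
    uvr <- project(rig$right, Xt[i, ])
    il <- nearest_row(cl, uvl, px_gate)
    ir <- nearest_row(cr, uvr, px_gate)
    if (is.na(il) || is.na(ir)) next
    est <- triangulate(rig, cl[il, ], cr[ir, ])$point
    rows[[length(rows) + 1]] <- tibble::tibble(
      dot = i, x = Xt[i, 1], y = Xt[i, 2], z = Xt[i, 3],
      est_x = est[1], est_y = est[2], est_z = est[3])
  }
  dots <- dplyr::bind_rows(rows)
  if (nrow(dots)) {
    dx <- dots$est_x - dots$x
    dy <- dots$est_y - dots$y
    dz <- dots$est_z - dots$z
    err3 <- sqrt(dx^2 + dy^2 + dz^2)
    dP <- sqrt(dx^2 + dy^2)  # in-plane (grid plane z = 0) component
    ok <- err3 <= gate_mm
    dots$dP_mm <- dP
    dots$err3d_mm <- err3
    dots <- dots[ok, ]
  }
  list(dots = dots,
       n_expected = nrow(Xt),
       n_detected_left = nrow(cl), n_detected_right = nrow(cr),
       n_matched = nrow(dots),
       shortfall = nrow(Xt) - nrow(dots))
}

nearest_row <- function(M, uv, gate) {
  if (nrow(M) == 0) return(NA_integer_)
  d2 <- (M[, 1] - uv[1])^2 + (M[, 2] - uv[2])^2
  i <- which.min(d2)
  if (sqrt(d2[i]) > gate) NA_integer_ else i
}
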