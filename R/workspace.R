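# Monte Carlo workspace estimation and simulated kinematic-error maps.

#' Monte Carlo reachable workspace
#'
#' Samples joint configurations uniformly within the joint limits (fixed
#' seed, mandatory for reproducibility), evaluates forward-kinematic
#' end-effector positions in batch, and voxelizes them. The reported volume
#' is `occupied_voxels * voxel_size^3`. When the reachable set is planar
#' (z-extent below one voxel) a planar `area` (`occupied_cells *
#' voxel_size^2`) is also reported, so planar test arms (2R annulus, rotary
#' circle) can be checked against closed forms.
#'
#' @param chain A [dh_chain()].
#' @param n_samples Number of joint samples (>= 0).
#' @param voxel_size Voxel edge length, mm.
#' @param seed Integer RNG seed (mandatory).
#' @return An object of class `workspace_estimate`: `points` (sample
#'   positions, possibly thinned for storage), `voxels` (tibble of occupied
#'   voxel centres with hit counts), `volume_mm3`, `area_mm2` (NA unless
#'   planar), `n_samples`, `voxel_size`, `seed`, `planar`.
#' @export
monte_carlo_workspace <- function(chain, n_samples, voxel_size, seed,
                                  keep_points = 10000L) {
  stopifnot(inherits(chain, "dh_chain"), n_samples >= 0, voxel_size > 0)
  seed <- as.integer(seed)
  if (n_samples == 0) {
    return(structure(list(points = matrix(numeric(0), 0, 3),
                          voxels = tibble::tibble(x = numeric(0), y = numeric(0),
                                                  z = numeric(0), hits = integer(0)),
                          volume_mm3 = 0, area_mm2 = 0, n_samples = 0L,
                          voxel_size = voxel_size, seed = seed, planar = TRUE),
                     class = "workspace_estimate"))
  }
  lims <- do.call(rbind, lapply(chain$links, function(l) l$limits))
  k <- nrow(lims)
  P <- withr::with_seed(seed, {
    Q <- matrix(stats::runif(n_samples * k), n_samples, k)
    Q <- sweep(sweep(Q, 2, lims[, 2] - lims[, 1], "*"), 2, lims[, 1], "+")
    fk_positions_batch(chain, Q)
  })
  idx <- floor(P / voxel_size)
  key <- paste(idx[, 1], idx[, 2], idx[, 3])
  tab <- table(key)
  first <- !duplicated(key)
  vox <- tibble::tibble(
    x = (idx[first, 1] + 0.5) * voxel_size,
    y = (idx[first, 2] + 0.5) * voxel_size,
    z = (idx[first, 3] + 0.5) * voxel_size,
    hits = as.integer(tab[key[first]])
  )
  zrange <- diff(range(P[, 3]))
  planar <- zrange < voxel_size
  keep <- if (nrow(P) > keep_points) {
    P[round(seq(1, nrow(P), length.out = keep_points)), , drop = FALSE]
  } else P
  structure(list(points = keep, voxels = vox,
                 volume_mm3 = nrow(vox) * voxel_size^3,
                 area_mm2 = if (planar) nrow(vox) * voxel_size^2 else NA_real_,
                 n_samples = as.integer(n_samples),
                 voxel_size = voxel_size, seed = seed, planar = planar),
            class = "workspace_estimate")
}

#' @export
print.workspace_estimate <- function(x, ...) {
  cat(sprintf(
    "<workspace_estimate> %d samples -> %d voxels (%.1f mm), volume %.4g mm^3%s\n",
    x$n_samples, nrow(x$voxels), x$voxel_size, x$volume_mm3,
    if (x$planar) sprintf(", planar area %.4g mm^2", x$area_mm2) else ""))
  invisible(x)
}

#' @param x A `workspace_estimate`.
#' @param ... Unused.
#' @rdname monte_carlo_workspace
#' @export
glance.workspace_estimate <- function(x, ...) {
  tibble::tibble(n_samples = x$n_samples, voxel_size = x$voxel_size,
                 n_voxels = nrow(x$voxels), volume_mm3 = x$volume_mm3,
                 area_mm2 = x$area_mm2, planar = x$planar, seed = x$seed)
}

#' Simulated kinematic-error map over the workspace
#'
#' Physical arms accumulate error along the serial chain; this simulates
#' that by perturbing the D-H parameters (independent Gaussian draws per
#' parameter) and mapping, on a regular grid spanning the workspace
#' (default 5 mm pitch), the mean end-effector displacement between nominal
#' and perturbed kinematics. The summary reports the fraction of grid cells
#' whose error falls below the 0.2 mm and 0.4 mm bands used to grade
#' workspace accuracy.
#'
#' @param chain A [dh_chain()].
#' @param sd_a,sd_d Perturbation standard deviations for link lengths and
#'   offsets, mm.
#' @param sd_alpha,sd_theta0 Perturbation standard deviations for twists and
#'   angle offsets, rad.
#' @param grid_pitch Grid pitch, mm (default 5).
#' @param n_config Joint configurations sampled to populate the grid.
#' @param n_draws Monte Carlo perturbation draws.
#' @param seed Integer RNG seed.
#' @return A list of class `kinematic_error_map`: `grid` (tibble with cell
#'   centres, mean error mm, hits), `summary` (tibble with fractions below
#'   0.2 / 0.4 mm), plus the call parameters.
#' @export
kinematic_error_map <- function(chain, sd_a = 0, sd_d = 0, sd_alpha = 0,
                                sd_theta0 = 0, grid_pitch = 5,
                                n_config = 20000L, n_draws = 20L, seed = 1L) {
  stopifnot(inherits(chain, "dh_chain"), grid_pitch > 0, n_config >= 1,
            n_draws >= 1)
  lims <- do.call(rbind, lapply(chain$links, function(l) l$limits))
  k <- nrow(lims)
  res <- withr::with_seed(as.integer(seed), {
    Q <- matrix(stats::runif(n_config * k), n_config, k)
    Q <- sweep(sweep(Q, 2, lims[, 2] - lims[, 1], "*"), 2, lims[, 1], "+")
    P0 <- fk_positions_batch(chain, Q)
    if (nrow(P0) == 0) stop("empty workspace")
    acc <- numeric(n_config)
    for (dr in seq_len(n_draws)) {
      pchain <- chain
      for (i in seq_len(k)) {
        l <- pchain$links[[i]]
        l$a <- l$a + stats::rnorm(1, 0, sd_a)
        l$d <- l$d + stats::rnorm(1, 0, sd_d)
        l$alpha <- l$alpha + stats::rnorm(1, 0, sd_alpha)
        l$theta0 <- l$theta0 + stats::rnorm(1, 0, sd_theta0)
        pchain$links[[i]] <- l
      }
      Pp <- fk_positions_batch(pchain, Q)
      acc <- acc + sqrt(rowSums((Pp - P0)^2))
    }
    list(P0 = P0, err = acc / n_draws)
  })
  idx <- floor(res$P0 / grid_pitch)
  key <- paste(idx[, 1], idx[, 2], idx[, 3])
  df <- tibble::tibble(key = key,
                       x = (idx[, 1] + 0.5) * grid_pitch,
                       y = (idx[, 2] + 0.5) * grid_pitch,
                       z = (idx[, 3] + 0.5) * grid_pitch,
                       err = res$err)
  grid <- dplyr::summarise(dplyr::group_by(df, key, x, y, z),
                           error_mm = mean(err), hits = dplyr::n(),
                           .groups = "drop")
  grid <- dplyr::select(grid, -"key")
  summary <- tibble::tibble(
    n_cells = nrow(grid),
    frac_below_0.2mm = mean(grid$error_mm < 0.2),
    frac_below_0.4mm = mean(grid$error_mm < 0.4),
    mean_error_mm = mean(grid$error_mm),
    max_error_mm = max(grid$error_mm)
  )
  structure(list(grid = grid, summary = summary, grid_pitch = grid_pitch,
                 sd = c(a = sd_a, d = sd_d, alpha = sd_alpha,
                        theta0 = sd_theta0),
                 n_config = n_config, n_draws = n_draws, seed = seed),
            class = "kinematic_error_map")
}

#' @export
print.kinematic_error_map <- function(x, ...) {
  cat(sprintf("<kinematic_error_map> pitch %.1f mm, %d cells\n",
              x$grid_pitch, nrow(x$grid)))
  print(x$summary)
  invisible(x)
}

#' Export workspace samples as an ASCII PLY point cloud
#' @param ws A `workspace_estimate`.
#' @param path Output path.
#' @export
write_workspace_ply <- function(ws, path) {
  stopifnot(inherits(ws, "workspace_estimate"))
  write_mesh(list(vertices = ws$points,
                  faces = matrix(integer(0), 0, 3), normals = NULL),
             path)
}
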