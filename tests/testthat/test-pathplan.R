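test_that("raster over a 10x10 square at 2 mm spacing has 6 scan lines", {
  sq <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  r <- plan_planar_raster(sq, 2)
  expect_equal(length(unique(r$scanline)), 6)   # floor(10/2) + 1
  # alternating direction
  x_by_line <- split(r$x, r$scanline)
  d1 <- diff(x_by_line[[1]]); d2 <- diff(x_by_line[[2]])
  expect_true(sign(d1[1]) != sign(d2[1]))
})

test_that("degenerate polygons are rejected", {
  expect_error(plan_planar_raster(cbind(c(0, 1), c(0, 0)), 1), "degenerate")
  expect_error(plan_planar_raster(cbind(c(0, 5, 10), c(0, 0, 0)), 1),
               "degenerate")
})

test_that("raster vertices stay inside a circular footprint", {
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  circ <- cbind(10 * cos(th), 10 * sin(th))
  r <- plan_planar_raster(circ, 1.5)
  expect_true(all(sqrt(r$x^2 + r$y^2) <= 10 + 1e-9))
})

test_that("raster coverage: interior points lie near the path", {
  sq <- cbind(c(0, 20, 20, 0), c(0, 0, 20, 20))
  spacing <- 2
  r <- plan_planar_raster(sq, spacing)
  set.seed(71)
  pts <- cbind(stats::runif(200, 1, 19), stats::runif(200, 1, 19))
  # distance from a point to the set of horizontal scan segments
  dmax <- max(apply(pts, 1, function(p) {
    min(abs(p[2] - unique(r$y)))
  }))
  expect_lte(dmax, spacing / sqrt(2) + 1e-9)
})

test_that("conformal projection on a flat mesh is the planar path with zero tilt", {
  xs <- seq(-10, 10, by = 1)
  g <- as.matrix(expand.grid(x = xs, y = xs))
  mesh <- reconstruct_surface(cbind(g, 0), grid_step = 1)
  path <- cbind(seq(-8, 8, by = 1), 0)
  tp <- project_conformal(path, mesh, step = 0.5)
  expect_lt(max(abs(tp$z)), 1e-9)
  expect_lt(max(abs(tp$pitch)), 1e-9)
  expect_lt(max(abs(tp$roll)), 1e-9)
  expect_lt(max(abs(tp$x[1] - (-8))), 1e-9)
})

test_that("conformal waypoints on the sphere cap lie on the analytic sphere with radial tool axes", {
  cap <- gen_sphere_cap(radius = 20, grid_step = 0.5, fraction = 0.7)
  sq <- cbind(c(-8, 8, 8, -8, -8), c(-8, -8, 8, 8, -8))
  ras <- plan_planar_raster(sq, 2)
  tp <- project_conformal(ras, cap, step = 0.5)
  r <- sqrt(tp$x^2 + tp$y^2 + tp$z^2)
  expect_lt(max(abs(r - 20)), 1e-6)
  for (i in seq_len(nrow(tp))) {
    R <- euler_to_rotation(tp$yaw[i], tp$pitch[i], tp$roll[i])
    n <- R[, 3]
    radial <- c(tp$x[i], tp$y[i], tp$z[i]) / r[i]
    expect_lt(acos(min(1, sum(n * radial))), 1e-6)
  }
})

test_that("conformal path length exceeds the planar length on a curved surface", {
  cap <- gen_sphere_cap(radius = 20, grid_step = 0.5, fraction = 0.7)
  path <- cbind(seq(-9, 9, by = 0.5), 0)
  tp <- project_conformal(path, cap, step = 0.5)
  len3d <- sum(sqrt(diff(tp$x)^2 + diff(tp$y)^2 + diff(tp$z)^2))
  expect_gt(len3d, 18)
})

test_that("samples outside the mesh raise a coverage error", {
  cap <- gen_sphere_cap(radius = 20, grid_step = 0.5, fraction = 0.5)
  path <- cbind(seq(-30, 30, by = 1), 0)
  expect_error(project_conformal(path, cap, step = 1), "coverage error")
})

test_that("bioink allocation is proportional to segment length and exact", {
  mk <- function(x) {
    toolpath(tibble::tibble(x = x, y = 0, z = 0, yaw = 0, pitch = 0,
                            roll = 0, extrude = 0, layer = 0L))
  }
  # two equal segments, 10 ul -> 5 each
  tp <- allocate_bioink(mk(c(0, 1, 2)), 10)
  expect_equal(tp$extrude, c(0, 5, 5))
  # lengths 1, 2, 3 -> 2, 4, 6 of 12
  tp2 <- allocate_bioink(mk(c(0, 1, 3, 6)), 12)
  expect_equal(tp2$extrude, c(0, 2, 4, 6))
  expect_identical(sum(tp2$extrude), 12)
  # zero volume
  tp3 <- allocate_bioink(mk(c(0, 1, 2)), 0)
  expect_true(all(tp3$extrude == 0))
  # empty path with positive volume
  empty <- toolpath(tibble::tibble(x = numeric(0), y = numeric(0),
                                   z = numeric(0), yaw = numeric(0),
                                   pitch = numeric(0), roll = numeric(0),
                                   extrude = numeric(0), layer = integer(0)))
  expect_error(allocate_bioink(empty, 5), "empty path")
})

test_that("point-to-point allocation splits equally by default and by weights", {
  pts <- toolpath(tibble::tibble(x = 1:4, y = 0, z = 0, yaw = 0, pitch = 0,
                                 roll = 0, extrude = 0, layer = 0L),
                  strategy = "point_to_point")
  tp <- allocate_bioink(pts, 10)
  expect_equal(tp$extrude, rep(2.5, 4))
  tp2 <- allocate_bioink(pts, 12, weights = c(1, 2, 3, 6))
  expect_equal(tp2$extrude, c(1, 2, 3, 6))
})

test_that("strategy selection follows the volume threshold with conformal ties", {
  expect_equal(choose_strategy(5, 20), "point_to_point")
  expect_equal(choose_strategy(30.92, 20), "conformal")
  expect_equal(choose_strategy(20, 20), "conformal")   # documented tie-break
})

test_that("printable range: 70-degree skid doubles to 140, normal-aligned gives 360", {
  expect_equal(printable_range(printability_model(70, "fixed_vertical")), 140)
  expect_equal(printable_range(printability_model(mode = "normal_aligned")), 360)
  expect_equal(printable_range(printability_model(90, "fixed_vertical")), 180)
  expect_error(printability_model(0), "skid_threshold")
})

test_that("plan_wound conserves the defect volume across layers", {
  cm <- gen_crater_mesh("hemisphere", radius = 5, grid_step = 0.25)
  model <- extract_wound(cm$mesh)
  tp <- plan_wound(model, line_spacing = 1, step = 0.5, layer_height = 0.5)
  expect_equal(attr(tp, "strategy"), "conformal")
  expect_lt(abs(sum(tp$extrude) - model$volume_mm3), 1e-9)
  expect_gt(length(unique(tp$layer)), 1)
  # small wound goes to point mode, still conserving volume
  cm2 <- gen_crater_mesh("punch_cylinder", radius = 2.5, depth = 1,
                         grid_step = 0.25)
  m2 <- extract_wound(cm2$mesh)
  tp2 <- plan_wound(m2)
  expect_equal(attr(tp2, "strategy"), "point_to_point")
  expect_lt(abs(sum(tp2$extrude) - m2$volume_mm3), 1e-9)
})

test_that("toolpath export writes JSON and the 6-axis dialect", {
  cm <- gen_crater_mesh("hemisphere", radius = 5, grid_step = 0.5)
  tp <- plan_wound(extract_wound(cm$mesh))
  fj <- tempfile(fileext = ".json"); fg <- tempfile(fileext = ".gcode")
  write_toolpath_json(tp, fj)
  write_toolpath_gcode(tp, fg)
  obj <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(nrow(obj$waypoints), nrow(tp))
  g <- readLines(fg)
  expect_true(any(grepl("^G1 X", g)))
  # cumulative extrusion on the last line equals the total volume
  lastE <- as.numeric(sub(".*E", "", g[length(g)]))
  expect_equal(lastE, sum(tp$extrude), tolerance = 1e-4)
})
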