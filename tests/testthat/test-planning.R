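test_that("ROI validation rejects degenerate and self-intersecting polygons", {
  expect_error(roi_polygon(rbind(c(0, 1e-3), c(1e-3, 1e-3))), ">= 3")
  expect_error(roi_polygon(rbind(c(0, 1e-3), c(1e-3, 1e-3), c(2e-3, 1e-3))),
               "zero area")
  expect_error(roi_polygon(rbind(c(0, 10e-3), c(4e-3, 10e-3),
                                 c(1e-3, 12e-3), c(3e-3, 12e-3))),
               "self-intersect")
  expect_error(roi_polygon(rbind(c(0, -1e-3), c(1e-3, 1e-3), c(0, 2e-3))),
               "z > 0")
})

test_that("bounding box encloses every vertex", {
  tri <- roi_polygon(rbind(c(0, 10e-3), c(4e-3, 10e-3), c(2e-3, 14e-3)))
  bb <- bounding_box(tri)
  expect_equal(unname(bb), c(0, 10e-3, 4e-3, 14e-3))
  r <- rect_roi(1e-3, 20e-3, 4e-3, 6e-3)
  expect_equal(unname(bounding_box(r)), c(-1e-3, 17e-3, 3e-3, 23e-3))
  # box area >= polygon area for arbitrary polygons
  set.seed(1)
  for (i in 1:20) {
    th <- sort(stats::runif(6, 0, 2 * pi))
    v <- cbind(cos(th), sin(th) + 3) * 5e-3 # star-convex, z > 0
    roi <- roi_polygon(v)
    bb <- bounding_box(roi)
    expect_gte((bb["x_max"] - bb["x_min"]) * (bb["z_max"] - bb["z_min"]),
               abs(fusbeam:::polygon_area(v)))
  }
})

test_that("f-number is depth over aperture width", {
  geom <- array_geometry()
  roi <- rect_roi(0, 30e-3, 4e-3, 4e-3)
  expect_equal(estimate_f_number(roi, geom), 30e-3 / 38.1e-3)
  # region centered at one aperture width of depth has f# 1
  roi1 <- rect_roi(0, 38.1e-3, 4e-3, 4e-3)
  expect_equal(estimate_f_number(roi1, geom), 1)
  # doubling the depth doubles the f-number
  roi2 <- rect_roi(0, 60e-3, 4e-3, 4e-3)
  expect_equal(estimate_f_number(roi2, geom),
               2 * estimate_f_number(rect_roi(0, 30e-3, 4e-3, 4e-3), geom))
})

test_that("planning params and steps follow the closed forms", {
  p <- planning_params(0.308e-3, 2)
  expect_equal(p$R_3dB, 0.886 * 0.308e-3 * 2)
  expect_equal(p$DOF_3dB, 7.1 * 0.308e-3 * 4)
  st <- grid_steps(p)
  expect_equal(unname(st["dx"]), 0.5458e-3, tolerance = 1e-4)
  expect_equal(unname(st["dz"]), 4.3736e-3, tolerance = 1e-4)
  # halving f#: dx halves, dz quarters
  st2 <- grid_steps(planning_params(0.308e-3, 1))
  expect_equal(unname(st2["dx"] / st["dx"]), 0.5)
  expect_equal(unname(st2["dz"] / st["dz"]), 0.25)
})

test_that("point_in_roi matches an independent winding-number oracle", {
  set.seed(7)
  hex <- roi_polygon(cbind(c(0, 2, 3, 2, 0, -1) * 1e-3,
                           c(10, 10, 12, 14, 14, 12) * 1e-3))
  expect_true(point_in_roi(colMeans(hex$vertices), hex))
  expect_false(point_in_roi(c(-5e-3, 12e-3), hex))
  pts <- cbind(stats::runif(1000, -2e-3, 4e-3), stats::runif(1000, 9e-3, 15e-3))
  mine <- apply(pts, 1, point_in_roi, roi = hex, tol = 0)
  oracle <- apply(pts, 1, winding_inside, v = hex$vertices)
  expect_identical(mine, oracle)
  # boundary points count as inside
  expect_true(point_in_roi(c(1e-3, 10e-3), hex))  # on an edge
  expect_true(point_in_roi(c(0, 10e-3), hex))     # on a vertex
})

test_that("focal grid matches the brute-force oracle on the 10x4 rectangle", {
  dx <- 0.5e-3; dz <- 2e-3
  roi <- rect_roi(0, 30e-3, 10 * dx, 4 * dz)
  fg <- generate_focal_grid(roi, dx, dz)
  oracle <- brute_force_grid(roi, dx, dz)
  expect_equal(nrow(fg$points), nrow(oracle))
  expect_equal(as.matrix(fg$points[, c("row", "x", "z")]), oracle,
               ignore_attr = TRUE, tolerance = 1e-12)
  # even rows 11 points, odd rows 10
  counts <- table(fg$points$row)
  expect_equal(unname(counts[c("0", "2", "4")]), rep(11L, 3), ignore_attr = TRUE)
  expect_equal(unname(counts[c("1", "3")]), rep(10L, 2), ignore_attr = TRUE)
  # odd-row offset exactly 0.5 dx from x_min
  bb <- bounding_box(roi)
  for (r in unique(fg$points$row)) {
    x0 <- min(fg$points$x[fg$points$row == r])
    expect_equal(x0 - bb[["x_min"]], if (r %% 2) 0.5 * dx else 0,
                 tolerance = 1e-12)
  }
  # row-major ordering, top row first, left to right
  expect_equal(fg$points$index, seq_len(nrow(fg$points)))
  expect_true(all(diff(fg$points$z) >= 0))
})

test_that("every emitted focal point lies inside the ROI (property)", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    th <- sort(stats::runif(n, 0, 2 * pi))
    rad <- stats::runif(n, 2e-3, 5e-3)
    v <- cbind(rad * cos(th), rad * sin(th) + 25e-3)
    roi <- roi_polygon(v)
    fg <- tryCatch(generate_focal_grid(roi, 0.7e-3, 1.3e-3),
                   error = function(e) NULL)
    if (is.null(fg)) next
    ok <- mapply(function(x, z) point_in_roi(c(x, z), roi),
                 fg$points$x, fg$points$z)
    expect_true(all(ok))
    # convex-ish ROIs: rows are contiguous runs of spacing dx
    for (r in unique(fg$points$row)) {
      xs <- fg$points$x[fg$points$row == r]
      if (length(xs) > 1 && !polygon_is_nonconvex(v)) {
        expect_equal(diff(xs), rep(0.7e-3, length(xs) - 1), tolerance = 1e-9)
      }
    }
  }
})

test_that("shrinking the ROI never adds focal points", {
  dx <- 0.6e-3; dz <- 1.5e-3
  big <- rect_roi(0, 30e-3, 8e-3, 8e-3)
  small <- rect_roi(0, 30e-3, 5e-3, 5e-3)
  fb <- generate_focal_grid(big, dx, dz)
  fs_ <- generate_focal_grid(small, dx, dz)
  expect_lte(nrow(fs_$points), nrow(fb$points))
})

test_that("a tiny ROI keeps only the first candidate or errors with guidance", {
  tri <- roi_polygon(rbind(c(-0.1e-3, 29.9e-3), c(0.4e-3, 29.9e-3),
                           c(0.1e-3, 30.3e-3)))
  fg <- generate_focal_grid(tri, 5e-3, 5e-3)
  expect_equal(nrow(fg$points), 1L)
  # tiny triangle avoiding its own bounding-box corner: no candidate survives
  tri2 <- roi_polygon(rbind(c(2.2e-3, 30e-3), c(2.4e-3, 30.3e-3),
                            c(2.0e-3, 30.3e-3)))
  expect_error(generate_focal_grid(tri2, 5e-3, 5e-3),
               "smaller than one focal cell")
})

test_that("ROI files round-trip with unit conversion", {
  roi <- rect_roi(0, 25e-3, 6e-3, 4e-3)
  f_mm <- withr::local_tempfile(fileext = ".csv")
  f_m <- withr::local_tempfile(fileext = ".csv")
  write_roi(roi, f_mm, units = "mm")
  write_roi(roi, f_m, units = "m")
  expect_equal(read_roi(f_mm)$vertices, roi$vertices, tolerance = 1e-12)
  expect_equal(read_roi(f_m)$vertices, roi$vertices, tolerance = 1e-12)
  # json form
  f_j <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(units = "mm",
                            vertices = roi$vertices * 1e3),
                       f_j, auto_unbox = TRUE, digits = NA)
  expect_equal(read_roi(f_j)$vertices, roi$vertices, tolerance = 1e-12)
})

test_that("plans round-trip through the text container", {
  geom <- array_geometry()
  p <- plan_therapy(rect_roi(0, 25e-3, 3e-3, 3e-3), geom)
  f <- withr::local_tempfile(fileext = ".txt")
  write_plan(p, f)
  back <- read_plan(f)
  expect_equal(back$points$x, p$grid$points$x)
  expect_equal(back$points$z, p$grid$points$z)
  expect_equal(back$dx, p$grid$dx)
})
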