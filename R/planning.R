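#' Region-of-interest polygon
#'
#' A closed, simple polygon on the image plane marking the treatment
#' region; the vertex list is implicitly closed. Coordinates are meters:
#' x lateral, z axial (depth).
#'
#' @param vertices n x 2 matrix (or two-column data frame) of (x, z).
#' @return An object of class `fus_roi`.
#' @export
roi_polygon <- function(vertices) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2 || nrow(v) < 3) stop("ROI needs >= 3 (x, z) vertices")
  storage.mode(v) <- "double"
  dimnames(v) <- NULL
  if (any(!is.finite(v))) stop("ROI vertices must be finite")
  if (any(v[, 2] <= 0)) stop("ROI must lie in front of the array (z > 0)")
  if (abs(polygon_area(v)) < .Machine$double.eps) {
    stop("degenerate ROI: polygon has zero area")
  }
  if (polygon_self_intersects(v)) stop("ROI polygon must not self-intersect")
  structure(list(vertices = v), class = "fus_roi")
}

# signed shoelace area
polygon_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2
}

segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

polygon_self_intersects <- function(v) {
  n <- nrow(v)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1 || (i == 1 && j == n)) next
      if (segments_cross(v[i, ], v[if (i == n) 1 else i + 1, ],
                         v[j, ], v[if (j == n) 1 else j + 1, ])) return(TRUE)
    }
  }
  FALSE
}

#' Axis-aligned bounding box of an ROI
#'
#' The smallest rectangle that completely encloses the treatment region.
#'
#' @param roi a [roi_polygon()].
#' @return named numeric `c(x_min, z_min, x_max, z_max)` (m).
#' @export
bounding_box <- function(roi) {
  stopifnot(inherits(roi, "fus_roi"))
  v <- roi$vertices
  c(x_min = min(v[, 1]), z_min = min(v[, 2]),
    x_max = max(v[, 1]), z_max = max(v[, 2]))
}

#' Point-in-ROI test (even-odd rule, boundary inclusive)
#'
#' Even-odd ray casting with a horizontal ray; points within `tol` of a
#' polygon edge count as inside.
#'
#' @param p numeric `c(x, z)`.
#' @param roi a [roi_polygon()].
#' @param tol boundary tolerance (m, default 1e-9).
#' @return logical.
#' @export
point_in_roi <- function(p, roi, tol = 1e-9) {
  v <- roi$vertices
  n <- nrow(v)
  x <- p[1]; z <- p[2]
  # boundary check: distance from p to each edge segment
  for (i in seq_len(n)) {
    a <- v[i, ]; b <- v[if (i == n) 1 else i + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / len2))
    if (sum((a + t * ab - p)^2) <= tol^2) return(TRUE)
  }
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    zi <- v[i, 2]; zj <- v[j, 2]
    if ((zi > z) != (zj > z)) {
      x_cross <- v[i, 1] + (z - zi) / (zj - zi) * (v[j, 1] - v[i, 1])
      if (x < x_cross) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Estimate the therapy beam f-number for an ROI
#'
#' Ratio of the depth of the region's center point (taken as the
#' bounding-box axial midpoint) to the lateral diameter of the imaging
#' array, `(n_elements - 1) * pitch`.
#'
#' @param roi a [roi_polygon()].
#' @param geom an [array_geometry()].
#' @return unitless f-number.
#' @export
estimate_f_number <- function(roi, geom) {
  bb <- bounding_box(roi)
  z_center <- (bb["z_min"] + bb["z_max"]) / 2
  unname(z_center / geom$aperture_width)
}

#' Closed-form focal-zone estimates and grid steps
#'
#' For a rectangular focusing source with continuous-wave excitation, the
#' -3 dB transmit beamwidth and depth of field are approximately
#' \deqn{R_{-3dB} = 0.886\,\lambda\,f_\#,\qquad
#'       DOF_{-3dB} = 7.1\,\lambda\,f_\#^2.}
#' The focal grid steps are `dx = R_3dB` and `dz = 0.5 * DOF_3dB`.
#'
#' @param lambda wavelength (m).
#' @param f_number unitless f-number.
#' @return `planning_params()`: list with `lambda`, `f_number`, `R_3dB`,
#'   `DOF_3dB`; `grid_steps()`: named `c(dx, dz)` (m).
#' @export
planning_params <- function(lambda, f_number) {
  stopifnot(lambda > 0, f_number > 0)
  structure(list(lambda = lambda, f_number = f_number,
                 R_3dB = 0.886 * lambda * f_number,
                 DOF_3dB = 7.1 * lambda * f_number^2),
            class = "fus_planning_params")
}

#' @rdname planning_params
#' @param params a [planning_params()].
#' @export
grid_steps <- function(params) {
  c(dx = params$R_3dB, dz = 0.5 * params$DOF_3dB)
}

#' Generate the focal-point grid for an ROI
#'
#' Candidate rows are laid at `z = z_min + k * dz` down through the
#' bounding box; even rows start at `x_min`, odd rows are offset by
#' `0.5 * dx` (reducing focal-zone overlap between adjacent rows), both
#' stepping `dx` while `x <= x_max` (with a 1e-9 m tie tolerance).
#' Candidates that do not fall within the ROI are discarded. Coordinates
#' stay continuous (no pixel snapping).
#'
#' @param roi a [roi_polygon()].
#' @param dx lateral step (m).
#' @param dz axial step (m).
#' @return A `fus_focal_grid`: data frame `points` (index, row, x, z) in
#'   row-major order (top row first, left to right), with `dx`, `dz`,
#'   `bounding_box` attributes.
#' @export
generate_focal_grid <- function(roi, dx, dz) {
  stopifnot(inherits(roi, "fus_roi"), dx > 0, dz > 0)
  bb <- bounding_box(roi)
  eps <- 1e-9
  pts <- list()
  k <- 0L
  repeat {
    z <- bb["z_min"] + k * dz
    if (z > bb["z_max"] + eps) break
    x0 <- bb["x_min"] + if (k %% 2L == 1L) 0.5 * dx else 0
    xs <- numeric(0)
    x <- x0
    while (x <= bb["x_max"] + eps) {
      xs <- c(xs, x)
      x <- x + dx
    }
    keep <- vapply(xs, function(xx) point_in_roi(c(xx, z), roi), logical(1))
    if (any(keep)) {
      pts[[length(pts) + 1L]] <- data.frame(row = k, x = xs[keep], z = unname(z))
    }
    k <- k + 1L
  }
  if (!length(pts)) {
    stop("no focal points survive: the ROI is smaller than one focal cell (",
         sprintf("dx = %.3g mm, dz = %.3g mm", dx * 1e3, dz * 1e3),
         "); enlarge the ROI or reduce the f-number")
  }
  tab <- do.call(rbind, pts)
  tab <- cbind(index = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  structure(list(points = tab, dx = unname(dx), dz = unname(dz),
                 bounding_box = bb),
            class = "fus_focal_grid")
}

#' @export
print.fus_focal_grid <- function(x, ...) {
  cat(sprintf("<fus_focal_grid> %d focal points in %d rows (dx %.3g mm, dz %.3g mm)\n",
              nrow(x$points), length(unique(x$points$row)),
              x$dx * 1e3, x$dz * 1e3))
  invisible(x)
}

#' Full therapy plan: ROI to focal grid
#'
#' Convenience wrapper running the planning pipeline: f-number from the
#' ROI depth, beamwidth/depth-of-field estimates at the array wavelength,
#' grid steps, focal grid.
#'
#' @param roi a [roi_polygon()].
#' @param geom an [array_geometry()].
#' @return list with `grid`, `params`, `f_number`.
#' @export
plan_therapy <- function(roi, geom) {
  fnum <- estimate_f_number(roi, geom)
  params <- planning_params(geom$wavelength, fnum)
  st <- grid_steps(params)
  list(grid = generate_focal_grid(roi, st["dx"], st["dz"]),
       params = params, f_number = fnum)
}

#' Read / write ROI vertex files
#'
#' Plain-text two-column table of vertices. A `# units=mm` (or `m`)
#' comment line declares the units; a JSON object `{"units": "mm",
#' "vertices": [[x, z], ...]}` is also accepted.
#'
#' @param path file path.
#' @return a [roi_polygon()], in meters.
#' @export
read_roi <- function(path) {
  first <- trimws(readLines(path, n = 1L))
  if (startsWith(first, "{")) {
    obj <- jsonlite::fromJSON(paste(readLines(path), collapse = "\n"))
    units <- obj$units %||% "m"
    v <- matrix(as.numeric(obj$vertices), ncol = 2)
  } else {
    units <- if (grepl("units\\s*=\\s*mm", first)) "mm"
             else if (grepl("units\\s*=\\s*m\\b", first)) "m"
             else "m"
    tab <- tryCatch(
      utils::read.table(path, comment.char = "#", header = FALSE),
      error = function(e) stop("malformed ROI file '", path, "': ",
                               conditionMessage(e)))
    if (ncol(tab) != 2) stop("ROI file must have exactly two columns (x, z)")
    v <- as.matrix(tab)
  }
  if (!units %in% c("m", "mm")) stop("ROI units must be 'm' or 'mm'")
  if (units == "mm") v <- v / 1e3
  roi_polygon(v)
}

#' @rdname read_roi
#' @param roi a [roi_polygon()].
#' @param units `"mm"` or `"m"` for the written file.
#' @export
write_roi <- function(roi, path, units = "mm") {
  scale <- if (units == "mm") 1e3 else 1
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fus_roi units=%s", units), con)
  utils::write.table(roi$vertices * scale, con, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a therapy plan table
#'
#' Tab-separated `index, row, x, z` table preceded by a one-line JSON
#' metadata header (`dx`, `dz`, `f_number`, `lambda`, bounding box).
#'
#' @param plan result of [plan_therapy()].
#' @param path file path.
#' @export
write_plan <- function(plan, path) {
  header <- list(type = "fus_plan", dx = plan$grid$dx, dz = plan$grid$dz,
                 f_number = plan$f_number, lambda = plan$params$lambda,
                 bounding_box = as.list(plan$grid$bounding_box))
  write_text_container(header, as.matrix(plan$grid$points), path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  tc <- read_text_container(path)
  if (!identical(tc$header$type, "fus_plan")) stop("not a fus_plan file")
  pts <- as.data.frame(tc$mat)
  names(pts) <- c("index", "row", "x", "z")
  structure(list(points = pts, dx = tc$header$dx, dz = tc$header$dz,
                 bounding_box = unlist(tc$header$bounding_box)),
            class = "fus_focal_grid")
}
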