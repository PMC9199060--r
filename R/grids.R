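#' Image pixel grid
#'
#' A rectangular pixel-center lattice shared by beamformed images and
#' intensity fields. Axes are strictly increasing; values matrices are
#' stored `[z, x]` (axial down the rows).
#'
#' @param x_axis lateral pixel centers (m).
#' @param z_axis axial pixel centers (m), all > 0.
#' @return An object of class `fus_grid`.
#' @export
image_grid <- function(x_axis, z_axis) {
  stopifnot(length(x_axis) >= 1, length(z_axis) >= 1)
  if (is.unsorted(x_axis, strictly = TRUE) || is.unsorted(z_axis, strictly = TRUE)) {
    stop("grid axes must be strictly increasing")
  }
  if (any(z_axis <= 0)) stop("grid depths must be positive (z > 0)")
  structure(list(x_axis = as.numeric(x_axis), z_axis = as.numeric(z_axis)),
            class = "fus_grid")
}

#' Default image grid for an array
#'
#' Axial spacing `c/(2*fs)` (one RF sample round trip), lateral spacing
#' one element pitch, spanning the given depth range and the full
#' aperture unless overridden.
#'
#' @param geom an [array_geometry()].
#' @param z_range depth range (m, length 2).
#' @param x_range lateral range (m); defaults to the aperture extent.
#' @export
default_grid <- function(geom, z_range = c(5e-3, 45e-3), x_range = NULL) {
  dz <- geom$c / (2 * geom$fs)
  x_range <- x_range %||% range(geom$element_x)
  image_grid(seq(x_range[1], x_range[2], by = geom$pitch),
             seq(z_range[1], z_range[2], by = dz))
}

grids_identical <- function(a, b, tol = 1e-12) {
  length(a$x_axis) == length(b$x_axis) && length(a$z_axis) == length(b$z_axis) &&
    max(abs(a$x_axis - b$x_axis)) <= tol && max(abs(a$z_axis - b$z_axis)) <= tol
}

#' Convert a nonnegative field to decibels relative to its maximum
#'
#' @param values nonnegative matrix (linear intensity scale).
#' @param floor_db values below this are clamped (default -120 dB).
#' @export
to_db <- function(values, floor_db = -120) {
  m <- max(values)
  if (m <= 0) stop("empty reconstruction: field has no positive values")
  pmax(10 * log10(pmax(values / m, 10^(floor_db / 10))), floor_db)
}
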