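#' Point-scatterer phantoms
#'
#' Builds the test phantoms used throughout the package: uniform speckle,
#' isolated point targets, a two-echogenicity-region phantom, and a
#' "bubble balloon" (a disk of strong scatterers inside an anechoic
#' water standoff above a speckle background). Scatterers are ideal
#' linear point reflectors; microbubbles are modeled only as strong
#' linear scatterers.
#'
#' Resolution-cell bookkeeping: for speckle-type regions the generator
#' places `density_per_cell` scatterers per resolution cell, with the cell
#' taken as (0.886 * lambda * f_number) laterally times half the pulse
#' spatial extent axially. Fully developed speckle needs >= 10 per cell;
#' the default is 12.
#'
#' @param kind `"speckle"`, `"points"`, `"two_region"` or `"balloon"`.
#' @param params named list; see Details.
#' @param rng_seed integer seed; identical seeds give identical phantoms.
#' @param geom an [array_geometry()], used only to size the resolution
#'   cell for speckle densities.
#' @param f_number f-number used to size the resolution cell (default 1).
#'
#' @details Common params: `x_range`, `z_range` (m, length-2) bound the
#' scattering region; `density_per_cell` (default 12); `mean_amp`
#' (default 1). Kind-specific:
#' \describe{
#'   \item{points}{`positions`: n x 2 matrix of (x, z); `amplitudes`
#'     (default 1).}
#'   \item{two_region}{`split_x` lateral boundary (default mid-range);
#'     `amp_ratio` region A (x < split) to region B amplitude ratio
#'     (default 2).}
#'   \item{balloon}{`gap_z` (m, length-2): anechoic standoff depth range
#'     containing the balloon; `disk_center`, `disk_radius`: the balloon;
#'     `disk_amp_ratio` balloon-to-background amplitude ratio (default
#'     10).}
#' }
#' @return A `fus_phantom`: `positions` (n x 2), `amplitudes`, `label`,
#'   `rng_seed`, and a `regions` list describing the geometry used.
#' @export
make_phantom <- function(kind = c("speckle", "points", "two_region", "balloon"),
                         params = list(), rng_seed = 1L,
                         geom = array_geometry(), f_number = 1) {
  kind <- match.arg(kind)
  p <- params
  p$x_range <- p$x_range %||% c(-5e-3, 5e-3)
  p$z_range <- p$z_range %||% c(20e-3, 30e-3)
  p$density_per_cell <- p$density_per_cell %||% 12
  p$mean_amp <- p$mean_amp %||% 1
  lambda <- geom$wavelength
  # resolution cell: -3 dB beamwidth x half pulse extent (2-cycle pulse)
  cell <- (0.886 * lambda * f_number) * (2 * lambda / 2)
  area <- diff(p$x_range) * diff(p$z_range)
  n_speckle <- max(1L, as.integer(round(p$density_per_cell * area / cell)))

  set.seed(as.integer(rng_seed))
  draw_speckle <- function(xr, zr, n) {
    cbind(stats::runif(n, xr[1], xr[2]), stats::runif(n, zr[1], zr[2]))
  }
  # reflectivity is a zero-mean fluctuation: amplitudes store the
  # magnitude (>= 0), polarity the sign, so dense speckle has no
  # coherent bulk (low-frequency) scattering component
  draw_polarity <- function(n) sample(c(-1, 1), n, replace = TRUE)
  regions <- list(x_range = p$x_range, z_range = p$z_range)
  pol <- NULL

  if (kind == "speckle") {
    pos <- draw_speckle(p$x_range, p$z_range, n_speckle)
    amp <- p$mean_amp * abs(stats::rnorm(n_speckle))
    pol <- draw_polarity(n_speckle)
  } else if (kind == "points") {
    if (is.null(p$positions)) stop("points phantom requires params$positions")
    pos <- matrix(as.numeric(p$positions), ncol = 2)
    amp <- rep_len(p$amplitudes %||% 1, nrow(pos))
    pol <- rep(1, nrow(pos))
  } else if (kind == "two_region") {
    split_x <- p$split_x %||% mean(p$x_range)
    ratio <- p$amp_ratio %||% 2
    pos <- draw_speckle(p$x_range, p$z_range, n_speckle)
    amp <- p$mean_amp * abs(stats::rnorm(n_speckle))
    pol <- draw_polarity(n_speckle)
    a_side <- pos[, 1] < split_x
    amp[a_side] <- amp[a_side] * ratio
    regions$split_x <- split_x
    regions$amp_ratio <- ratio
  } else { # balloon
    gap_z <- p$gap_z %||% c(p$z_range[1], p$z_range[1] + 0.4 * diff(p$z_range))
    if (gap_z[1] < p$z_range[1] - 1e-12 || gap_z[2] > p$z_range[2] + 1e-12) {
      stop("balloon gap_z must lie inside z_range (overlapping exclusive regions)")
    }
    ctr <- p$disk_center %||% c(mean(p$x_range), mean(gap_z))
    rad <- p$disk_radius %||% (0.3 * diff(gap_z))
    if (ctr[2] - rad < gap_z[1] - 1e-12 || ctr[2] + rad > gap_z[2] + 1e-12) {
      stop("balloon disk must fit inside the anechoic gap")
    }
    ratio <- p$disk_amp_ratio %||% 10
    # speckle background strictly below the anechoic gap
    bg_n <- max(1L, as.integer(round(
      p$density_per_cell * diff(p$x_range) * (p$z_range[2] - gap_z[2]) / cell)))
    bg <- draw_speckle(p$x_range, c(gap_z[2], p$z_range[2]), bg_n)
    bg_amp <- p$mean_amp * abs(stats::rnorm(bg_n))
    # disk of strong scatterers (rejection sample inside the circle)
    disk_n <- max(1L, as.integer(round(
      p$density_per_cell * pi * rad^2 / cell)))
    dpos <- matrix(numeric(0), ncol = 2)
    while (nrow(dpos) < disk_n) {
      cand <- cbind(stats::runif(2 * disk_n, -rad, rad),
                    stats::runif(2 * disk_n, -rad, rad))
      cand <- cand[rowSums(cand^2) <= rad^2, , drop = FALSE]
      dpos <- rbind(dpos, cand)
    }
    dpos <- dpos[seq_len(disk_n), , drop = FALSE]
    dpos[, 1] <- dpos[, 1] + ctr[1]
    dpos[, 2] <- dpos[, 2] + ctr[2]
    pos <- rbind(bg, dpos)
    amp <- c(bg_amp, ratio * p$mean_amp * abs(stats::rnorm(disk_n)))
    pol <- draw_polarity(bg_n + disk_n)
    regions$gap_z <- gap_z
    regions$disk_center <- ctr
    regions$disk_radius <- rad
    regions$disk_amp_ratio <- ratio
  }
  if (any(pos[, 2] <= 0)) stop("all scatterers must lie in front of the array (z > 0)")
  structure(list(positions = pos, amplitudes = as.numeric(amp),
                 polarity = as.numeric(pol), label = kind,
                 rng_seed = as.integer(rng_seed), regions = regions),
            class = "fus_phantom")
}

#' @export
print.fus_phantom <- function(x, ...) {
  cat(sprintf("<fus_phantom> '%s': %d scatterers, seed %d\n",
              x$label, nrow(x$positions), x$rng_seed))
  invisible(x)
}

#' Combine two phantoms
#'
#' Concatenates scatterer lists; used by linearity checks and to compose
#' scenes.
#' @param a,b `fus_phantom` objects.
#' @export
combine_phantoms <- function(a, b) {
  structure(list(positions = rbind(a$positions, b$positions),
                 amplitudes = c(a$amplitudes, b$amplitudes),
                 polarity = c(a$polarity, b$polarity),
                 label = paste(a$label, b$label, sep = "+"),
                 rng_seed = a$rng_seed,
                 regions = list(a = a$regions, b = b$regions)),
            class = "fus_phantom")
}

#' Write / read a phantom as a plain-text table
#'
#' Tab-separated columns `x`, `z`, `amplitude` (SI units) preceded by a
#' `# label=<label> seed=<seed>` comment line and a header line.
#' @param phantom a `fus_phantom`.
#' @param path file path.
#' @export
write_phantom <- function(phantom, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fus_phantom label=%s seed=%d",
                     phantom$label, phantom$rng_seed), con)
  writeLines("x\tz\tamplitude\tpolarity", con)
  utils::write.table(
    data.frame(x = phantom$positions[, 1], z = phantom$positions[, 2],
               amplitude = phantom$amplitudes,
               polarity = phantom$polarity %||% rep(1, nrow(phantom$positions))),
    con, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phantom
#' @param path file path.
#' @export
read_phantom <- function(path) {
  first <- readLines(path, n = 1L)
  label <- sub(".*label=(\\S+).*", "\\1", first)
  seed <- as.integer(sub(".*seed=(-?\\d+).*", "\\1", first))
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  structure(list(positions = cbind(tab$x, tab$z),
                 amplitudes = tab$amplitude,
                 polarity = tab$polarity %||% rep(1, nrow(tab)),
                 label = label, rng_seed = seed, regions = list()),
            class = "fus_phantom")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
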