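# replicate-padded moving-average box filter (separable, cumsum-based)
box_filter_replicate <- function(m, kz, kx) {
  pad_rows <- function(a, k) {
    h <- (k - 1) / 2
    if (h == 0) return(a)
    rbind(a[rep(1, h), , drop = FALSE], a, a[rep(nrow(a), h), , drop = FALSE])
  }
  run_mean_rows <- function(a, k) {
    if (k == 1) return(a)
    cs <- apply(a, 2, cumsum)
    cs <- rbind(0, cs)
    (cs[(k + 1):nrow(cs), , drop = FALSE] - cs[1:(nrow(cs) - k), , drop = FALSE]) / k
  }
  m <- run_mean_rows(pad_rows(m, kz), kz)
  t(run_mean_rows(pad_rows(t(m), kx), kx))
}

odd_kernel_px <- function(extent, spacing) {
  n <- max(1L, as.integer(round(extent / spacing)))
  if (n %% 2L == 0L) n + 1L else n
}

#' Smooth a B-mode envelope into an echogenicity map
#'
#' Moving-average filter spanning 5.5 wavelengths laterally by 7
#' wavelengths axially (rounded to odd pixel counts, replicate-padded
#' borders), so speckle and small features do not drive the
#' normalization. Pixels whose smoothed envelope sits 60 dB or more
#' below the image maximum are flagged as noise.
#'
#' @param envelope a `fus_image` of kind `"bmode_envelope"`.
#' @param lambda_wave acoustic wavelength (m) setting the kernel size.
#' @param noise_floor_db mask threshold below the maximum (default 60).
#' @return A `fus_echo_map`: smoothed `B`, `B_max`, logical
#'   `noise_mask`, kernel sizes, and the grid.
#' @export
smooth_bmode <- function(envelope, lambda_wave, noise_floor_db = 60) {
  stopifnot(inherits(envelope, "fus_image"))
  if (!identical(envelope$kind, "bmode_envelope")) {
    stop("smooth_bmode expects a bmode_envelope image")
  }
  gx <- envelope$grid$x_axis; gz <- envelope$grid$z_axis
  dx <- if (length(gx) > 1) gx[2] - gx[1] else lambda_wave
  dz <- if (length(gz) > 1) gz[2] - gz[1] else lambda_wave
  kx <- odd_kernel_px(5.5 * lambda_wave, dx)
  kz <- odd_kernel_px(7 * lambda_wave, dz)
  if (kx > ncol(envelope$values) || kz > nrow(envelope$values)) {
    stop(sprintf("smoothing kernel (%d x %d px) larger than the image (%d x %d px)",
                 kz, kx, nrow(envelope$values), ncol(envelope$values)))
  }
  B <- box_filter_replicate(envelope$values, kz, kx)
  B_max <- max(B)
  mask <- if (B_max > 0) 20 * log10(pmax(B, .Machine$double.xmin) / B_max) <=
    -noise_floor_db else matrix(TRUE, nrow(B), ncol(B))
  structure(list(B = B, B_max = B_max, noise_mask = mask,
                 kernel_px = c(z = kz, x = kx), grid = envelope$grid,
                 source = envelope),
            class = "fus_echo_map")
}

#' Echogenicity normalization factor
#'
#' Per-pixel factor `B_max / B[x, z]` that equalizes the FUS beam
#' reconstruction across regions of different scattering strength.
#' Noise-mask pixels (60 dB or more below `B_max`) are not amplified:
#' their factor is the identity 1, so beam dropout in anechoic regions
#' emerges from the low backscatter itself.
#'
#' @param map a [smooth_bmode()] result.
#' @return matrix of factors, all >= 1.
#' @export
normalization_factor <- function(map) {
  stopifnot(inherits(map, "fus_echo_map"))
  if (map$B_max <= 0) stop("empty image: B_max is zero")
  f <- map$B_max / pmax(map$B, .Machine$double.xmin)
  f[map$noise_mask] <- 1
  pmax(f, 1)
}

#' Apply an echogenicity normalization to a beamformed image
#'
#' @param image a `fus_image` (visualization RF).
#' @param factor matrix from [normalization_factor()].
#' @return a `fus_image` with scaled values.
#' @export
apply_normalization <- function(image, factor) {
  stopifnot(inherits(image, "fus_image"),
            all(dim(image$values) == dim(factor)))
  out <- image
  out$values <- image$values * factor
  out
}

#' Pulse intensity integral of a beamformed visualization image
#'
#' Sliding sum of squared (normalized) beamformed RF over the transmit
#' pulse length:
#' \deqn{I[x,z] = \sum_{i=0}^{L-1} \Delta z_s\, |y_{norm}[x, z+i]|^2,}
#' truncated at the bottom edge of the image, where `L` is the transmit
#' pulse length in samples and `dz_s` the axial sample period of the
#' grid. The result is also stored in dB normalized to its maximum.
#'
#' @param y_norm a `fus_image` (visualization RF, normalization already
#'   applied).
#' @param L pulse length in samples (see [pulse_length_samples()]).
#' @param dz_s axial sample period (m); defaults to the grid spacing.
#' @return A `fus_field` of kind `"reconstructed"`.
#' @export
intensity_field <- function(y_norm, L, dz_s = NULL) {
  stopifnot(inherits(y_norm, "fus_image"))
  L <- as.integer(L)
  if (L < 1) stop("pulse length L must be >= 1 sample")
  gz <- y_norm$grid$z_axis
  if (is.null(dz_s)) {
    dz_s <- if (length(gz) > 1) gz[2] - gz[1] else stop("dz_s required")
  }
  y2 <- y_norm$values^2
  nz <- nrow(y2)
  cs <- rbind(0, apply(y2, 2, cumsum))
  upper <- pmin(seq_len(nz) + L - 1L, nz) # window truncated at bottom edge
  I <- dz_s * (cs[upper + 1L, , drop = FALSE] - cs[seq_len(nz), , drop = FALSE])
  fld <- new_field(I, y_norm$grid, kind = "reconstructed")
  fld$pulse_length_L <- L
  fld$axial_sample_period <- dz_s
  fld
}

#' Average intensity fields over a therapy session
#'
#' Pixel-wise mean of the linear-scale, per-frame max-normalized fields,
#' re-normalized to its own maximum: the session-level picture of the
#' energy delivered across the whole focal grid.
#'
#' @param fields nonempty list of `fus_field`s on a shared grid.
#' @return A `fus_field` of kind `"reconstructed"`.
#' @export
average_intensity <- function(fields) {
  if (!length(fields)) stop("average_intensity needs at least one field")
  g0 <- fields[[1]]$grid
  acc <- matrix(0, nrow(fields[[1]]$values), ncol(fields[[1]]$values))
  for (f in fields) {
    if (!grids_identical(f$grid, g0)) stop("all fields must share a grid")
    m <- max(f$values)
    if (m <= 0) stop("empty reconstruction in field list")
    acc <- acc + f$values / m
  }
  new_field(acc / length(fields), g0, kind = "reconstructed")
}

#' Overlay an intensity field on its co-registered B-mode
#'
#' The B-mode is rendered in grayscale over `bmode_range_db`; field
#' pixels within `dyn_range_db` of the field's 0 dB peak are overlaid in
#' a hot colormap. Deterministic: the same inputs always produce the
#' same composite.
#'
#' @param map a [smooth_bmode()] result (its source envelope is drawn).
#' @param field a `fus_field` on the same grid.
#' @param dyn_range_db overlay dynamic range below the peak (default 10).
#' @param bmode_range_db B-mode display range (default 60).
#' @return A `fus_overlay`: `bmode_db`, `field_db`, logical `mask` of
#'   overlaid pixels, display ranges, grid.
#' @export
overlay <- function(map, field, dyn_range_db = 10, bmode_range_db = 60) {
  stopifnot(inherits(map, "fus_echo_map"), inherits(field, "fus_field"))
  if (!grids_identical(map$grid, field$grid)) {
    stop("B-mode and intensity field grids do not match")
  }
  env <- map$source$values
  emax <- max(env)
  bdb <- 20 * log10(pmax(env, .Machine$double.xmin) / max(emax, .Machine$double.xmin))
  bdb <- pmax(bdb, -bmode_range_db)
  mask <- field$db >= -dyn_range_db
  structure(list(bmode_db = bdb, field_db = field$db, mask = mask,
                 dyn_range_db = dyn_range_db, bmode_range_db = bmode_range_db,
                 grid = field$grid),
            class = "fus_overlay")
}

#' Intensity-weighted centroid of the overlaid region
#' @param ov a [overlay()] result.
#' @return `c(x, z)` in m.
#' @export
overlay_centroid <- function(ov) {
  w <- ifelse(ov$mask, 10^(ov$field_db / 10), 0)
  tot <- sum(w)
  c(sum(outer(rep(1, nrow(w)), ov$grid$x_axis) * w) / tot,
    sum(outer(ov$grid$z_axis, rep(1, ncol(w))) * w) / tot)
}

#' @export
plot.fus_overlay <- function(x, ...) {
  gx <- x$grid$x_axis * 1e3; gz <- x$grid$z_axis * 1e3
  graphics::image(gx, gz, t(x$bmode_db),
                  col = grDevices::gray.colors(256, 0, 1), useRaster = TRUE,
                  xlab = "lateral x (mm)", ylab = "depth z (mm)",
                  ylim = rev(range(gz)), ...)
  fd <- x$field_db
  fd[!x$mask] <- NA
  graphics::image(gx, gz, t(fd),
                  col = grDevices::hcl.colors(64, "Inferno"),
                  useRaster = TRUE, add = TRUE)
  invisible(x)
}

#' Save an overlay composite to PNG
#' @param ov a [overlay()] result.
#' @param path output PNG path.
#' @param width,height device size in pixels.
#' @export
save_overlay_png <- function(ov, path, width = 640, height = 480) {
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  plot(ov)
  invisible(path)
}
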