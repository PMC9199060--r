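#' Two-way receive delay for a pixel
#'
#' Delay-and-sum time delay for image point `(x, z)` seen by a receive
#' element at lateral position `x_e`:
#' \deqn{\tau[x,z] = \tau_F + (z + \sqrt{z^2 + (x - x_e)^2})/c,}
#' where `tau_F` is the transmit delay applied to the center element of
#' the receive subaperture (the one-way transmit leg is approximated as
#' `tau_F + z/c`).
#'
#' @param x,z pixel coordinates (m), `z > 0`.
#' @param x_e receive element lateral position (m).
#' @param tau_f transmit delay of the subaperture center element (s).
#' @param c speed of sound (m/s).
#' @return delay in seconds.
#' @export
rx_delay <- function(x, z, x_e, tau_f, c) {
  stopifnot(z > 0)
  tau_f + (z + sqrt(z^2 + (x - x_e)^2)) / c
}

#' Dynamic receive aperture
#'
#' Constant-f-number receive aperture: width `w = z / f_number` centered
#' on the element nearest the pixel's lateral position, so the half-count
#' is `floor(w / (2 * pitch))`; the range is clipped to the physical
#' array (N >= 1).
#'
#' @param x pixel lateral position (m).
#' @param z pixel depth (m).
#' @param f_number receive f-number (1 maintains constant-f# imaging).
#' @param geom an [array_geometry()].
#' @return list `first`, `last` (1-based element indices), `n`, `center`.
#' @export
dynamic_aperture <- function(x, z, f_number, geom) {
  stopifnot(z > 0, f_number > 0)
  ic <- floor((x - geom$element_x[1]) / geom$pitch + 0.5) + 1
  ic <- min(max(ic, 1), geom$n_elements)
  k <- floor((z / f_number) / (2 * geom$pitch))
  first <- max(1, ic - k)
  last <- min(geom$n_elements, ic + k)
  list(first = as.integer(first), last = as.integer(last),
       n = as.integer(last - first + 1), center = as.integer(ic))
}

hann_window <- function(n) {
  if (n <= 2) return(rep(1, n)) # symmetric Hann degenerates to zeros
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

# per-pixel transmit delay to the pixel for a focused transmit event:
# tau_F of the element nearest each pixel column, plus z/c
focused_tx_delay_map <- function(geom, tx_delays, grid) {
  ic <- pmin(pmax(floor((grid$x_axis - geom$element_x[1]) / geom$pitch + 0.5) + 1, 1),
             geom$n_elements)
  outer(grid$z_axis / geom$c, tx_delays[ic], `+`)
}

planewave_tx_delay_map <- function(geom, angle_deg, grid) {
  th <- angle_deg * pi / 180
  off <- -min(geom$element_x * sin(th)) / geom$c
  outer(grid$z_axis * cos(th) / geom$c, grid$x_axis * sin(th) / geom$c, `+`) + off
}

#' Gather delayed subaperture samples (reference implementation)
#'
#' Per-pixel, per-channel delay-and-gather: channel k's RF linearly
#' interpolated at its [rx_delay()] time, over that pixel's
#' [dynamic_aperture()]. Times outside the record contribute 0. This is
#' the plain-R reference route; [beamform_image()] is the fast compiled
#' path and must agree with the pipeline built from this function.
#'
#' @param data a `fus_channel_data`.
#' @param grid an [image_grid()].
#' @param f_number receive f-number (default 1).
#' @param tx_delay_map optional per-pixel transmit delay matrix
#'   (`[z, x]`); defaults to the focused law using the transmit event's
#'   own delays.
#' @return list with `s` (list-matrix free form: per-pixel numeric
#'   vectors), `n`, `aperture` bookkeeping; consumed by
#'   [das_gcf_image()].
#' @export
delay_and_gather <- function(data, grid, f_number = 1, tx_delay_map = NULL) {
  stopifnot(inherits(data, "fus_channel_data"), inherits(grid, "fus_grid"))
  geom <- data$geom
  if (is.null(tx_delay_map)) {
    tx_delay_map <- focused_tx_delay_map(geom, data$tx_meta$delays, grid)
  }
  nt <- ncol(data$rf)
  nx <- length(grid$x_axis); nz <- length(grid$z_axis)
  s <- vector("list", nz * nx)
  dim(s) <- c(nz, nx)
  nmat <- matrix(0L, nz, nx)
  for (ix in seq_len(nx)) {
    for (iz in seq_len(nz)) {
      ap <- dynamic_aperture(grid$x_axis[ix], grid$z_axis[iz], f_number, geom)
      idx <- ap$first:ap$last
      # one-way tx leg is tau_tx - z/c + z/c: rx_delay adds the z/c term
      tau <- rx_delay(grid$x_axis[ix], grid$z_axis[iz], geom$element_x[idx],
                      tx_delay_map[iz, ix] - grid$z_axis[iz] / geom$c, geom$c)
      u <- (tau - data$t0) * data$fs
      v <- numeric(length(idx))
      ok <- u >= 0 & u <= nt - 1
      if (any(ok)) {
        m <- floor(u[ok])
        f <- u[ok] - m
        a <- data$rf[cbind(idx[ok], m + 1)]
        b <- ifelse(m < nt - 1, data$rf[cbind(idx[ok], pmin(m + 2, nt))], a)
        v[ok] <- a * (1 - f) + b * f
      }
      s[[iz, ix]] <- v
      nmat[iz, ix] <- ap$n
    }
  }
  list(s = s, n = nmat, grid = grid)
}

#' Generalized coherence factor of a delayed subaperture column
#'
#' Fraction of the subaperture spectrum's energy within `M` bins of DC:
#' \deqn{GCF = \frac{\sum_{k=-M}^{M} |S[k]|^2}{N \sum_k |s[k]|^2},}
#' with `S` the length-N DFT across channels and negative bins taken
#' modulo N. Coherent (constant) columns give 1, fully alternating
#' columns give 0, and the Parseval bound keeps the value in [0, 1].
#' `N = 1` returns 1 by convention; a zero-energy column returns 0. When
#' `N` is small, `M` is capped at `floor((N-1)/2)` so wrapped bins are
#' never counted twice.
#'
#' @param s_column numeric vector of N delayed channel samples.
#' @param M half-width of the low-frequency band (default 2).
#' @return weight in [0, 1].
#' @export
gcf <- function(s_column, M = 2) {
  N <- length(s_column)
  stopifnot(N >= 1, M >= 0)
  if (N == 1) return(1)
  denom <- N * sum(s_column^2)
  if (denom <= 0) return(0)
  S <- stats::fft(s_column)
  Meff <- min(M, (N - 1) %/% 2)
  bins <- unique((seq(-Meff, Meff) %% N) + 1)
  min(sum(Mod(S[bins])^2) / denom, 1)
}

#' DAS-GCF image from gathered subaperture data (reference route)
#'
#' \deqn{y[x,z] = GCF[x,z] \sum_i w[i]\, s_{[x,z]}[i]}
#' with `w` a Hann window regenerated per subaperture length N (the GCF
#' is computed on the unwindowed samples).
#'
#' @param sub result of [delay_and_gather()].
#' @param M GCF band half-width (default 2); `NA` disables GCF (plain
#'   DAS).
#' @return A `fus_image` of kind `"visualization_rf"`.
#' @export
das_gcf_image <- function(sub, M = 2) {
  nz <- nrow(sub$n); nx <- ncol(sub$n)
  y <- matrix(0, nz, nx)
  g <- matrix(1, nz, nx)
  for (ix in seq_len(nx)) {
    for (iz in seq_len(nz)) {
      s <- sub$s[[iz, ix]]
      w <- hann_window(length(s))
      das <- sum(w * s)
      if (!is.na(M)) {
        g[iz, ix] <- gcf(s, M)
        y[iz, ix] <- g[iz, ix] * das
      } else {
        y[iz, ix] <- das
      }
    }
  }
  img <- new_image(y, sub$grid, kind = "visualization_rf")
  img$gcf <- g
  img
}

new_image <- function(values, grid, kind) {
  structure(list(values = values, grid = grid, kind = kind),
            class = "fus_image")
}

#' @export
print.fus_image <- function(x, ...) {
  cat(sprintf("<fus_image> %s, %d x %d pixels\n", x$kind,
              ncol(x$values), nrow(x$values)))
  invisible(x)
}

#' Beamform channel data (fast path)
#'
#' Compiled DAS beamformer with dynamic receive focusing, dynamic
#' constant-f# aperture, Hann apodization and optional GCF weighting.
#' Identical math to the [delay_and_gather()] + [das_gcf_image()]
#' reference route.
#'
#' @param data a `fus_channel_data`.
#' @param grid an [image_grid()].
#' @param f_number receive f-number (default 1).
#' @param M GCF band half-width; `NA` for plain DAS.
#' @param tx_delay_map optional per-pixel transmit delay matrix.
#' @return A `fus_image` of kind `"visualization_rf"` (with `$gcf`).
#' @export
beamform_image <- function(data, grid, f_number = 1, M = 2,
                           tx_delay_map = NULL) {
  stopifnot(inherits(data, "fus_channel_data"), inherits(grid, "fus_grid"))
  geom <- data$geom
  if (is.null(tx_delay_map)) {
    tx_delay_map <- focused_tx_delay_map(geom, data$tx_meta$delays, grid)
  }
  res <- .cpp_das(data$rf, data$t0, data$fs, geom$element_x, tx_delay_map,
                  grid$x_axis, grid$z_axis, geom$c, f_number,
                  if (is.na(M)) 0L else as.integer(M), !is.na(M))
  img <- new_image(res$y, grid, kind = "visualization_rf")
  img$gcf <- res$gcf
  img$nsub <- res$nsub
  img
}

# analytic-signal magnitude along each image column (depth direction)
envelope_columns <- function(y) {
  nz <- nrow(y)
  h <- numeric(nz)
  if (nz %% 2 == 0) {
    h[c(1, nz / 2 + 1)] <- 1
    h[2:(nz / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((nz + 1) / 2)] <- 2
  }
  apply(y, 2, function(col) Mod(stats::fft(stats::fft(col) * h, inverse = TRUE) / nz))
}

#' Coherent plane-wave compounded B-mode
#'
#' Per-angle DAS with the steered plane-wave transmit delay law
#' `(z cos(theta) + x sin(theta))/c` (referenced so the element delay
#' minimum is 0) plus the receive path, constant-f# (default 1) dynamic
#' receive aperture and Hann apodization; the per-angle RF images are
#' summed coherently and envelope-detected as the magnitude of the
#' analytic signal along depth. GCF is not applied on the B-mode path.
#'
#' @param frames list of `fus_channel_data`, one per steering angle.
#' @param angles_deg the steering angles; must be evenly spaced and
#'   symmetric (the full compounding set, e.g. 11 angles from -18 to 18).
#' @param grid an [image_grid()].
#' @param f_number receive f-number (default 1).
#' @return A `fus_image` of kind `"bmode_envelope"` (with `$rf_sum`).
#' @export
pwc_bmode <- function(frames, angles_deg, grid, f_number = 1) {
  if (length(frames) != length(angles_deg)) {
    stop("coherent compounding requires one frame per steering angle; got ",
         length(frames), " frames for ", length(angles_deg), " angles")
  }
  if (length(angles_deg) > 1) {
    d <- diff(sort(angles_deg))
    if (max(abs(d - d[1])) > 1e-9 ||
        abs(max(angles_deg) + min(angles_deg)) > 1e-9) {
      stop("steering angles must be evenly spaced and symmetric about 0")
    }
  }
  geom <- frames[[1]]$geom
  acc <- NULL
  for (i in seq_along(frames)) {
    tx_map <- planewave_tx_delay_map(geom, angles_deg[i], grid)
    res <- .cpp_das(frames[[i]]$rf, frames[[i]]$t0, frames[[i]]$fs,
                    geom$element_x, tx_map, grid$x_axis, grid$z_axis,
                    geom$c, f_number, 0L, FALSE)
    acc <- if (is.null(acc)) res$y else acc + res$y
  }
  img <- new_image(envelope_columns(acc), grid, kind = "bmode_envelope")
  img$rf_sum <- acc
  img
}
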