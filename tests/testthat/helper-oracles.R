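# Independent oracles used against the implementation routes.

# winding-number point-in-polygon (independent of the even-odd ray caster)
winding_inside <- function(p, v) {
  n <- nrow(v)
  w <- 0
  for (i in seq_len(n)) {
    a <- v[i, ]
    b <- v[if (i == n) 1 else i + 1, ]
    cross <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    if (a[2] <= p[2]) {
      if (b[2] > p[2] && cross > 0) w <- w + 1
    } else {
      if (b[2] <= p[2] && cross < 0) w <- w - 1
    }
  }
  w != 0
}

# brute-force focal-grid oracle: enumerate candidate rows/columns over the
# bounding box and keep candidates inside the polygon
brute_force_grid <- function(roi, dx, dz) {
  bb <- bounding_box(roi)
  eps <- 1e-9
  out <- NULL
  k <- 0
  repeat {
    z <- bb["z_min"] + k * dz
    if (z > bb["z_max"] + eps) break
    x <- bb["x_min"] + if (k %% 2 == 1) 0.5 * dx else 0
    while (x <= bb["x_max"] + eps) {
      if (point_in_roi(c(x, z), roi)) out <- rbind(out, c(k, x, z))
      x <- x + dx
    }
    k <- k + 1
  }
  out
}

# direct-summation GCF oracle (explicit complex DFT, no fft())
gcf_brute <- function(s, M) {
  N <- length(s)
  if (N == 1) return(1)
  denom <- N * sum(s^2)
  if (denom <= 0) return(0)
  Meff <- min(M, (N - 1) %/% 2)
  ks <- unique((-Meff):Meff %% N)
  num <- 0
  for (k in ks) {
    Sk <- sum(s * exp(-2i * pi * k * (0:(N - 1)) / N))
    num <- num + Mod(Sk)^2
  }
  min(num / denom, 1)
}

# direct (loop) replicate-padded moving average
box_smooth_brute <- function(m, kz, kx) {
  hz <- (kz - 1) / 2; hx <- (kx - 1) / 2
  nz <- nrow(m); nx <- ncol(m)
  out <- matrix(0, nz, nx)
  for (i in seq_len(nz)) {
    for (j in seq_len(nx)) {
      acc <- 0
      for (a in (i - hz):(i + hz)) {
        for (b in (j - hx):(j + hx)) {
          acc <- acc + m[min(max(a, 1), nz), min(max(b, 1), nx)]
        }
      }
      out[i, j] <- acc / (kz * kx)
    }
  }
  out
}

small_geom <- function(n = 32L) array_geometry(n_elements = n, pitch = 0.3e-3)

rect_roi <- function(xc, zc, w, h) {
  roi_polygon(rbind(c(xc - w / 2, zc - h / 2), c(xc + w / 2, zc - h / 2),
                    c(xc + w / 2, zc + h / 2), c(xc - w / 2, zc + h / 2)))
}

polygon_is_nonconvex <- function(v) {
  n <- nrow(v)
  s <- sign(vapply(seq_len(n), function(i) {
    a <- v[i, ]; b <- v[(i %% n) + 1, ]; cc <- v[((i + 1) %% n) + 1, ]
    (b[1] - a[1]) * (cc[2] - a[2]) - (b[2] - a[2]) * (cc[1] - a[1])
  }, numeric(1)))
  length(unique(s[s != 0])) > 1
}

# interpolated extent of a profile above level * max (level 0.25 = -6 dB
# for intensity profiles)
level_extent <- function(axis, prof, level) {
  pk <- which.max(prof)
  th <- prof[pk] * level
  lo <- axis[1]
  hi <- axis[length(axis)]
  if (pk > 1) {
    b <- which(prof[seq_len(pk - 1)] < th)
    if (length(b)) {
      i <- max(b)
      lo <- axis[i] + (axis[i + 1] - axis[i]) * (th - prof[i]) /
        (prof[i + 1] - prof[i])
    }
  }
  if (pk < length(prof)) {
    a <- which(prof[seq(pk + 1, length(prof))] < th)
    if (length(a)) {
      i <- pk + min(a)
      hi <- axis[i - 1] + (axis[i] - axis[i - 1]) * (th - prof[i - 1]) /
        (prof[i] - prof[i - 1])
    }
  }
  hi - lo
}
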