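#' Linear imaging array geometry
#'
#' Describes a 1-D linear probe: element positions along the lateral (x)
#' axis, centered on 0, with the array face at axial depth z = 0. The
#' default matches a 128-element, 0.3 mm pitch, 5 MHz probe (38.1 mm
#' aperture) sampled at four samples per wavelength.
#'
#' @param n_elements number of elements.
#' @param pitch element center-to-center spacing (m).
#' @param f0 center frequency (Hz).
#' @param fs RF sampling rate (Hz); must be at least `4 * f0`.
#' @param c speed of sound (m/s). 1540 m/s is the soft-tissue default;
#'   use 1480 m/s for water-standoff scenes.
#' @param element_width acoustic element width (m) setting the
#'   strip-element directivity `sinc(w sin(theta)/lambda) cos(theta)`
#'   applied by the simulator on transmit and receive. Defaults to the
#'   pitch (kerfless element); 0 gives omnidirectional point elements.
#' @return An object of class `fus_array` with fields `n_elements`,
#'   `pitch`, `element_x`, `f0`, `fs`, `c`, `aperture_width`,
#'   `wavelength`, `element_width`.
#' @examples
#' geom <- array_geometry()
#' geom$aperture_width # 38.1 mm
#' @export
array_geometry <- function(n_elements = 128L, pitch = 0.3e-3, f0 = 5e6,
                           fs = 20e6, c = 1540, element_width = pitch) {
  n_elements <- as.integer(n_elements)
  stopifnot(n_elements >= 1L, pitch > 0, f0 > 0, c > 0)
  if (fs < 4 * f0) {
    stop("fs = ", fs, " Hz violates the Nyquist-margin constraint fs >= 4*f0 ",
         "(need >= ", 4 * f0, " Hz for ~4 samples per wavelength)")
  }
  element_x <- (seq_len(n_elements) - (n_elements + 1) / 2) * pitch
  structure(
    list(n_elements = n_elements, pitch = pitch, element_x = element_x,
         f0 = f0, fs = fs, c = c,
         aperture_width = (n_elements - 1) * pitch,
         wavelength = c / f0, element_width = element_width),
    class = "fus_array")
}

#' @export
print.fus_array <- function(x, ...) {
  cat(sprintf(
    "<fus_array> %d elements, pitch %.3g mm, aperture %.3g mm, f0 %.3g MHz, fs %.3g MHz, c %g m/s\n",
    x$n_elements, x$pitch * 1e3, x$aperture_width * 1e3, x$f0 / 1e6,
    x$fs / 1e6, x$c))
  invisible(x)
}

#' Pulse specification
#'
#' A tone-burst excitation: `n_cycles` cycles of a sinusoid at `frequency`.
#' The therapy burst is 160 cycles and the beam-visualization pulse 2
#' cycles, both at the array center frequency.
#'
#' @param frequency pulse frequency (Hz).
#' @param n_cycles number of cycles (>= 1).
#' @param kind one of `"therapy"`, `"visualization"`, `"imaging"`.
#' @param taper burst envelope: `"rect"` (untapered tone burst, the
#'   therapy/visualization default) or `"hann"`.
#' @return An object of class `fus_pulse`.
#' @export
pulse_spec <- function(frequency = 5e6, n_cycles = 2L,
                       kind = c("visualization", "therapy", "imaging"),
                       taper = c("rect", "hann")) {
  kind <- match.arg(kind)
  taper <- match.arg(taper)
  stopifnot(frequency > 0, n_cycles >= 1)
  structure(list(frequency = frequency, n_cycles = n_cycles, kind = kind,
                 taper = taper),
            class = "fus_pulse")
}

#' Pulse length in samples
#'
#' `L = round(n_cycles * fs / frequency)`: the transmit pulse length in RF
#' samples, used as the sliding-window length of the pulse intensity
#' integral.
#'
#' @param pulse a [pulse_spec()].
#' @param fs sampling rate (Hz).
#' @return integer sample count.
#' @export
pulse_length_samples <- function(pulse, fs) {
  as.integer(round(pulse$n_cycles * fs / pulse$frequency))
}

#' Sample a tone burst
#'
#' Returns `n_cycles` cycles of a sine at the pulse frequency, sampled at
#' `fs`, peak amplitude 1. The default envelope is rectangular (an untapered
#' tone burst); `taper = "hann"` applies a Hann taper over the full burst.
#'
#' @param pulse a [pulse_spec()].
#' @param fs sampling rate (Hz); must satisfy `fs >= 4 * frequency`.
#' @param taper `"rect"` or `"hann"`; defaults to the pulse's own taper.
#' @return numeric vector of `round(n_cycles * fs / frequency)` samples.
#' @examples
#' length(make_tone_burst(pulse_spec(5e6, 160, "therapy"), 20e6)) # 640
#' @export
make_tone_burst <- function(pulse, fs, taper = NULL) {
  stopifnot(inherits(pulse, "fus_pulse"))
  taper <- match.arg(taper %||% pulse$taper %||% "rect", c("rect", "hann"))
  if (fs < 4 * pulse$frequency) {
    stop("fs = ", fs, " Hz undersamples a ", pulse$frequency,
         " Hz burst: the Nyquist-margin constraint fs >= 4*frequency requires fs >= ",
         4 * pulse$frequency, " Hz")
  }
  L <- pulse_length_samples(pulse, fs)
  if (L < 2) stop("pulse shorter than 2 samples at fs = ", fs, " Hz")
  t <- (seq_len(L) - 1) / fs
  w <- sin(2 * pi * pulse$frequency * t)
  if (taper == "hann") {
    w <- w * (0.5 - 0.5 * cos(2 * pi * (seq_len(L) - 1) / (L - 1)))
  }
  w
}

#' Focused-transmit element delays
#'
#' Per-element transmit delays that make every element's wavefront arrive
#' at the focal point simultaneously:
#' `delay[i] = (max_j r_j - r_i) / c`, where `r_i` is the distance from
#' element i to the focus. The minimum delay is 0.
#'
#' @param geom an [array_geometry()].
#' @param focal_point numeric `c(x, z)` in m; `z > 0`.
#' @return numeric vector of delays (s), one per element.
#' @export
focus_delays <- function(geom, focal_point) {
  stopifnot(inherits(geom, "fus_array"), length(focal_point) == 2)
  if (focal_point[2] <= 0) {
    stop("focal depth must be positive (z = ", focal_point[2], " m)")
  }
  r <- sqrt((geom$element_x - focal_point[1])^2 + focal_point[2]^2)
  (max(r) - r) / geom$c
}

#' Steered plane-wave element delays
#'
#' Linear delay law for a plane wave steered `angle_deg` degrees off the
#' axial direction: `delay[i] = (element_x[i] * sin(angle) - min)/c`, so
#' the minimum delay is 0.
#'
#' @param geom an [array_geometry()].
#' @param angle_deg steering angle in degrees, `|angle| < 90`.
#' @return numeric vector of delays (s), one per element.
#' @export
planewave_delays <- function(geom, angle_deg) {
  stopifnot(inherits(geom, "fus_array"))
  if (abs(angle_deg) >= 90) stop("|steering angle| must be < 90 degrees")
  d <- geom$element_x * sin(angle_deg * pi / 180)
  (d - min(d)) / geom$c
}
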