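#' Therapy/monitoring excitation configuration
#'
#' The interleaved treat/monitor schedule: each focal point receives a
#' 50 ms treatment window (160-cycle, 5 MHz tone bursts at a 3 kHz pulse
#' repetition frequency) followed by a 2 s imaging window in which a
#' 2-cycle focused visualization pulse and an 11-angle (+-18 degrees)
#' plane-wave compounded B-mode frame are captured.
#'
#' @param treat_window treatment window duration (s, default 0.050).
#' @param prf therapy pulse repetition frequency (Hz, default 3000).
#' @param therapy_pulse a [pulse_spec()] (default 160 cycles at 5 MHz).
#' @param image_window imaging window duration (s, default 2).
#' @param vis_pulse a [pulse_spec()] (default 2 cycles at 5 MHz).
#' @param imaging_pulse a [pulse_spec()] for the plane-wave B-mode
#'   frames (default a Hann-tapered 3-cycle burst at 5 MHz; the tapered
#'   envelope keeps the wideband plane-wave point response's diagonal
#'   ridge artifacts ~15 dB lower than an untapered burst, which the
#'   echogenicity normalization needs).
#' @param n_pwc_angles number of compounding angles (default 11).
#' @param max_angle_deg steering extent (default 18: angles span -18..18).
#' @param frames_per_image_window visualize+B-mode repetitions per image
#'   window (default 1; hardware repeats for the full window, one frame
#'   is enough to reconstruct).
#' @return A `fus_therapy_config`.
#' @export
therapy_config <- function(treat_window = 0.050, prf = 3000,
                           therapy_pulse = pulse_spec(5e6, 160L, "therapy"),
                           image_window = 2.0,
                           vis_pulse = pulse_spec(5e6, 2L, "visualization"),
                           imaging_pulse = pulse_spec(5e6, 3L, "imaging",
                                                      taper = "hann"),
                           n_pwc_angles = 11L, max_angle_deg = 18,
                           frames_per_image_window = 1L) {
  stopifnot(treat_window > 0, image_window > 0, prf > 0,
            n_pwc_angles >= 1, frames_per_image_window >= 1)
  n_bursts <- treat_window * prf
  if (abs(n_bursts - round(n_bursts)) > 1e-9) {
    stop("treat_window * prf must be a whole number of bursts (got ",
         n_bursts, ")")
  }
  structure(list(treat_window = treat_window, prf = prf,
                 therapy_pulse = therapy_pulse, image_window = image_window,
                 vis_pulse = vis_pulse, imaging_pulse = imaging_pulse,
                 n_pwc_angles = as.integer(n_pwc_angles),
                 max_angle_deg = max_angle_deg,
                 frames_per_image_window = as.integer(frames_per_image_window),
                 n_bursts = as.integer(round(n_bursts))),
            class = "fus_therapy_config")
}

#' Compounding angles of a configuration
#' @param cfg a [therapy_config()].
#' @export
pwc_angles <- function(cfg) {
  if (cfg$n_pwc_angles == 1) return(0)
  seq(-cfg$max_angle_deg, cfg$max_angle_deg, length.out = cfg$n_pwc_angles)
}

#' Build the interleaved treat/monitor event schedule
#'
#' For each focal point in grid order: one treatment window (its burst
#' count logged), then `frames_per_image_window` visualize + B-mode
#' pairs; timestamps accumulate the window durations.
#'
#' @param grid a `fus_focal_grid`.
#' @param cfg a [therapy_config()].
#' @return data frame of events: `kind` (treat/visualize/bmode),
#'   `point_index`, `time` (s), `n_bursts`.
#' @export
build_sequence <- function(grid, cfg) {
  stopifnot(inherits(grid, "fus_focal_grid"), inherits(cfg, "fus_therapy_config"))
  if (nrow(grid$points) < 1) stop("focal grid is empty")
  events <- list()
  t <- 0
  frame_dt <- cfg$image_window / cfg$frames_per_image_window
  for (i in grid$points$index) {
    events[[length(events) + 1L]] <-
      data.frame(kind = "treat", point_index = i, time = t,
                 n_bursts = cfg$n_bursts)
    t <- t + cfg$treat_window
    for (f in seq_len(cfg$frames_per_image_window)) {
      events[[length(events) + 1L]] <-
        data.frame(kind = "visualize", point_index = i, time = t, n_bursts = 0L)
      events[[length(events) + 1L]] <-
        data.frame(kind = "bmode", point_index = i, time = t + frame_dt / 2,
                   n_bursts = 0L)
      t <- t + frame_dt
    }
  }
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out
}

#' Run a mock FUS therapy session on a simulated phantom
#'
#' Executes the full planned sequence against the linear RF simulator:
#' for every focal point, a 2-cycle visualization pulse is transmitted
#' (focused at that point), the backscatter is beamformed with DAS-GCF,
#' normalized by the echogenicity of a co-registered plane-wave
#' compounded B-mode, and integrated into a pulse intensity field.
#' Treatment bursts are schedule-only (no bioeffect model). The phantom
#' is static, so the B-mode capture is computed once and reused at every
#' image window (each window still logs a bmode event).
#'
#' @param phantom a [make_phantom()] result.
#' @param geom an [array_geometry()].
#' @param grid a `fus_focal_grid` from [plan_therapy()].
#' @param cfg a [therapy_config()].
#' @param seed integer master seed; every random draw derives from it.
#' @param image_grid an [image_grid()]; default covers the focal grid
#'   with a margin.
#' @param noise_sd channel noise standard deviation (default 0).
#' @param M GCF band half-width (default 2).
#' @return A `fus_session`: `events` log, per-point `fields`, `averaged`
#'   field, `echo_map`, `norm_factor`, inputs and seeds.
#' @export
run_mock_session <- function(phantom, geom, grid, cfg = therapy_config(),
                             seed = 1L, image_grid = NULL, noise_sd = 0,
                             M = 2) {
  stopifnot(inherits(grid, "fus_focal_grid"))
  pts <- grid$points
  if (is.null(image_grid)) {
    xr <- range(pts$x) + c(-3e-3, 3e-3)
    zr <- pmax(range(pts$z) + c(-4e-3, 4e-3), geom$wavelength)
    image_grid <- default_grid(geom, z_range = zr, x_range = xr)
  }
  if (min(pts$z) < min(image_grid$z_axis) - 1e-9 ||
      max(pts$z) > max(image_grid$z_axis) + 1e-9 ||
      min(pts$x) < min(image_grid$x_axis) - 1e-9 ||
      max(pts$x) > max(image_grid$x_axis) + 1e-9) {
    stop("focal point outside the reconstruction grid; enlarge image_grid")
  }
  events <- build_sequence(grid, cfg)
  vis_wave <- make_tone_burst(cfg$vis_pulse, geom$fs)
  L <- pulse_length_samples(cfg$vis_pulse, geom$fs)

  # one B-mode capture per session (static phantom)
  angles <- pwc_angles(cfg)
  imaging_wave <- make_tone_burst(cfg$imaging_pulse, geom$fs)
  frames <- lapply(seq_along(angles), function(i) {
    synthesize_channel_data(
      phantom, geom, planewave_delays(geom, angles[i]), imaging_wave,
      noise_sd = noise_sd, tx_meta = list(kind = "planewave",
                                          angle_deg = angles[i]),
      seed = (seed * 131L + i) %% .Machine$integer.max)
  })
  bmode <- pwc_bmode(frames, angles, image_grid)
  emap <- smooth_bmode(bmode, geom$wavelength)
  nf <- normalization_factor(emap)

  fields <- vector("list", nrow(pts))
  for (row in seq_len(nrow(pts))) {
    fp <- c(pts$x[row], pts$z[row])
    cd <- synthesize_channel_data(
      phantom, geom, focus_delays(geom, fp), vis_wave, noise_sd = noise_sd,
      tx_meta = list(kind = "focused", focus = fp),
      seed = (seed * 977L + row) %% .Machine$integer.max)
    y <- beamform_image(cd, image_grid, f_number = 1, M = M)
    fields[[row]] <- intensity_field(apply_normalization(y, nf), L)
  }
  structure(list(events = events, fields = fields,
                 averaged = average_intensity(fields),
                 echo_map = emap, norm_factor = nf, grid = grid,
                 image_grid = image_grid, cfg = cfg, geom = geom,
                 seed = as.integer(seed), noise_sd = noise_sd,
                 status = "complete"),
            class = "fus_session")
}

#' @export
print.fus_session <- function(x, ...) {
  cat(sprintf("<fus_session> %d focal points, %d events, %.1f s simulated (%s)\n",
              nrow(x$grid$points), nrow(x$events),
              nrow(x$grid$points) * (x$cfg$treat_window + x$cfg$image_window),
              x$status))
  invisible(x)
}

#' Compare therapy and visualization excitation beams
#'
#' Simulates the incident intensity field of the long therapy burst and
#' the short visualization pulse focused at the same point and reports
#' their -3 dB beamwidths, depths of field, and ratios
#' (visualization / therapy). Ratios near 1 establish that the short
#' pulse is a faithful stand-in for the therapy beam.
#'
#' @param geom an [array_geometry()].
#' @param focus `c(x, z)` focal point (m).
#' @param cfg a [therapy_config()].
#' @param grid optional metrics [image_grid()]; by default the two
#'   metrics are measured on narrow lateral/axial strips through the
#'   focus (the full 2-D field is not needed for a beamwidth and a
#'   depth of field, and long therapy bursts are expensive to
#'   superpose).
#' @return list with per-pulse metrics and `beamwidth_ratio`,
#'   `dof_ratio`.
#' @export
compare_excitations <- function(geom, focus, cfg = therapy_config(),
                                grid = NULL) {
  fnum <- focus[2] / geom$aperture_width
  bw <- 0.886 * geom$wavelength * fnum
  dof <- 7.1 * geom$wavelength * fnum^2
  txd <- focus_delays(geom, focus)
  one <- function(pulse) {
    wave <- make_tone_burst(pulse, geom$fs)
    if (!is.null(grid)) {
      f <- simulate_incident_intensity(geom, txd, wave, grid)
      return(measure_beam_metrics(f, focus)[c("beamwidth", "dof")])
    }
    lat <- image_grid(seq(focus[1] - 4 * bw, focus[1] + 4 * bw, by = bw / 12),
                      focus[2] + c(-1, 0, 1) * dof / 60)
    axi <- image_grid(focus[1] + c(-1, 0, 1) * bw / 12,
                      seq(max(focus[2] - 2.5 * dof, geom$wavelength),
                          focus[2] + 2.5 * dof, by = dof / 40))
    list(beamwidth = measure_beam_metrics(
           simulate_incident_intensity(geom, txd, wave, lat), focus)$beamwidth,
         dof = measure_beam_metrics(
           simulate_incident_intensity(geom, txd, wave, axi), focus)$dof)
  }
  m_therapy <- one(cfg$therapy_pulse)
  m_vis <- one(cfg$vis_pulse)
  list(therapy = m_therapy, visualization = m_vis,
       beamwidth_ratio = m_vis$beamwidth / m_therapy$beamwidth,
       dof_ratio = m_vis$dof / m_therapy$dof, f_number = fnum)
}

#' Re-plan a paused session on a new treatment region
#'
#' Reruns the full planning pipeline on the new ROI and restarts the
#' schedule at the new grid's first point; the completed event log is
#' retained untouched.
#'
#' @param session a `fus_session`.
#' @param new_roi a [roi_polygon()].
#' @param geom an [array_geometry()].
#' @return list with the original `session`, the new `grid`, `params`,
#'   and the resumed `schedule` (new events, timestamps restarting after
#'   the completed log).
#' @export
replan <- function(session, new_roi, geom) {
  stopifnot(inherits(session, "fus_session"))
  if (!inherits(new_roi, "fus_roi")) {
    stop("new_roi must be a validated roi_polygon(); session unchanged")
  }
  p <- plan_therapy(new_roi, geom) # invalid ROI errors here, session untouched
  sched <- build_sequence(p$grid, session$cfg)
  sched$time <- sched$time + if (nrow(session$events)) {
    max(session$events$time) + session$cfg$image_window
  } else 0
  list(session = session, grid = p$grid, params = p$params, schedule = sched)
}
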