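test_that("single active element places one echo replica at the two-way delay", {
  geom <- array_geometry(n_elements = 8, pitch = 0.3e-3)
  target <- c(0.5e-3, 10e-3)
  ph <- make_phantom("points", list(positions = rbind(target)), 1, geom)
  wave <- make_tone_burst(pulse_spec(5e6, 2), geom$fs)
  apod <- replace(rep(0, 8), 3, 1)
  cd <- synthesize_channel_data(ph, geom, rep(0, 8), wave, tx_apod = apod)
  r3 <- sqrt((geom$element_x[3] - target[1])^2 + target[2]^2)
  m_exp <- (2 * r3 / geom$c) * geom$fs
  onset <- which(abs(cd$rf[3, ]) > 1e-6 * max(abs(cd$rf[3, ])))[1]
  expect_lt(abs(onset - m_exp), 2.5) # replica onset at round((2r/c)fs)
  # monostatic amplitude ~ a/r^2 (normal incidence, directivity ~ 1)
  expect_equal(max(abs(cd$rf[3, ])), 1 / r3^2, tolerance = 0.1)
  # echo support is one replica long (plus interpolation tails)
  nz <- range(which(abs(cd$rf[3, ]) > 1e-6 * max(abs(cd$rf[3, ]))))
  expect_lt(diff(nz), length(wave) + 4)
})

test_that("zero-amplitude phantoms and channel-data validation behave", {
  geom <- small_geom(16)
  ph <- make_phantom("points", list(positions = rbind(c(0, 10e-3)),
                                    amplitudes = 0), 1, geom)
  wave <- make_tone_burst(pulse_spec(5e6, 2), geom$fs)
  cd <- synthesize_channel_data(ph, geom, rep(0, 16), wave, noise_sd = 0)
  expect_true(all(cd$rf == 0))
  bad <- ph
  bad$positions[1, 2] <- -1e-3
  expect_error(synthesize_channel_data(bad, geom, rep(0, 16), wave), "behind")
  expect_error(synthesize_channel_data(ph, geom, rep(0, 16), numeric(0)),
               "nonempty")
  expect_error(synthesize_channel_data(ph, geom, rep(0, 4), wave),
               "per element")
})

test_that("channel data is linear in the phantom and deterministic", {
  geom <- small_geom(16)
  wave <- make_tone_burst(pulse_spec(5e6, 2), geom$fs)
  txd <- focus_delays(geom, c(0, 15e-3))
  pa <- make_phantom("points", list(positions = rbind(c(-1e-3, 14e-3)),
                                    amplitudes = 1.3), 1, geom)
  pb <- make_phantom("points", list(positions = rbind(c(1e-3, 16e-3)),
                                    amplitudes = 0.7), 1, geom)
  n <- 700L
  ca <- synthesize_channel_data(pa, geom, txd, wave, n_samples = n)
  cb <- synthesize_channel_data(pb, geom, txd, wave, n_samples = n)
  cab <- synthesize_channel_data(combine_phantoms(pa, pb), geom, txd, wave,
                                 n_samples = n)
  expect_equal(cab$rf, ca$rf + cb$rf, tolerance = 1e-12)
  # identical seeds => bit-identical noisy records
  n1 <- synthesize_channel_data(pa, geom, txd, wave, noise_sd = 1, seed = 42,
                                n_samples = n)
  n2 <- synthesize_channel_data(pa, geom, txd, wave, noise_sd = 1, seed = 42,
                                n_samples = n)
  expect_identical(n1$rf, n2$rf)
})

test_that("echo arrival is reciprocal under tx/rx element swap", {
  geom <- array_geometry(n_elements = 6, pitch = 0.5e-3)
  ph <- make_phantom("points", list(positions = rbind(c(0.7e-3, 12e-3))), 1, geom)
  wave <- make_tone_burst(pulse_spec(5e6, 2), geom$fs)
  one_hot <- function(i) replace(rep(0, 6), i, 1)
  # transmit on 2, receive on 5 vs transmit on 5, receive on 2
  a <- synthesize_channel_data(ph, geom, rep(0, 6), wave,
                               tx_apod = one_hot(2), n_samples = 600L)
  b <- synthesize_channel_data(ph, geom, rep(0, 6), wave,
                               tx_apod = one_hot(5), n_samples = 600L)
  # identical arrival time; amplitudes agree to interpolation error
  expect_equal(which.max(abs(a$rf[5, ])), which.max(abs(b$rf[2, ])))
  expect_lt(max(abs(a$rf[5, ] - b$rf[2, ])) / max(abs(a$rf[5, ])), 0.05)
})

test_that("two symmetric scatterers give element-reversal-symmetric rf", {
  geom <- array_geometry(n_elements = 16, pitch = 0.3e-3)
  ph <- make_phantom("points",
                     list(positions = rbind(c(-1.2e-3, 20e-3),
                                            c(1.2e-3, 20e-3))), 1, geom)
  wave <- make_tone_burst(pulse_spec(5e6, 2), geom$fs)
  cd <- synthesize_channel_data(ph, geom, focus_delays(geom, c(0, 20e-3)), wave)
  expect_equal(cd$rf, cd$rf[rev(seq_len(16)), ], tolerance = 1e-10)
})

test_that("incident field of a single element is radially symmetric", {
  geom <- array_geometry(n_elements = 1, pitch = 0.3e-3)
  wave <- make_tone_burst(pulse_spec(5e6, 2), geom$fs)
  grid <- image_grid(seq(-2e-3, 2e-3, by = 0.5e-3), seq(4e-3, 8e-3, by = 0.25e-3))
  f <- simulate_incident_intensity(geom, 0, wave, grid,
                                   tx_apod = 1)
  # compare mirrored lateral positions at fixed depth (same radius/angle)
  expect_equal(f$values[, 1], f$values[, ncol(f$values)], tolerance = 1e-9)
  expect_true(all(f$values >= 0))
})

test_that("beam metrics recover a synthetic Gaussian and are scale-invariant", {
  gx <- seq(-3e-3, 3e-3, by = 2e-5)
  gz <- seq(18e-3, 26e-3, by = 5e-5)
  grid <- image_grid(gx, gz)
  sig_x <- 0.4e-3; sig_z <- 1.1e-3
  vals <- outer(gz, gx, function(z, x)
    exp(-(x^2) / (2 * sig_x^2) - ((z - 22e-3)^2) / (2 * sig_z^2)))
  f <- fusbeam:::new_field(vals, grid, "incident")
  m <- measure_beam_metrics(f, c(0, 22e-3))
  expect_equal(m$beamwidth, 2 * sig_x * sqrt(2 * log(2)), tolerance = 2e-5 / m$beamwidth)
  expect_equal(m$dof, 2 * sig_z * sqrt(2 * log(2)), tolerance = 5e-5 / m$dof)
  f2 <- fusbeam:::new_field(vals * 37.5, grid, "incident")
  m2 <- measure_beam_metrics(f2, c(0, 22e-3))
  expect_equal(m2$beamwidth, m$beamwidth)
  expect_equal(m2$dof, m$dof)
  expect_warning(measure_beam_metrics(f, c(2.5e-3, 19e-3)), "not near")
  expect_error(measure_beam_metrics(f, c(10e-3, 22e-3)), "outside")
})

test_that("focused incident beam peaks at the geometric focus", {
  # full 128-element aperture (strong focusing: high Fresnel number keeps
  # the diffraction focal shift below a wavelength)
  geom <- array_geometry()
  focus <- c(0, 20e-3)
  wave <- make_tone_burst(pulse_spec(5e6, 20, "therapy"), geom$fs)
  grid <- image_grid(seq(-1e-3, 1e-3, by = 5e-5), seq(18e-3, 22e-3, by = 5e-5))
  f <- simulate_incident_intensity(geom, focus_delays(geom, focus), wave, grid)
  expect_lt(sqrt(sum((field_peak(f) - focus)^2)), geom$wavelength)
})

test_that("beam metrics converge to the closed forms across f-number", {
  # CW-like burst, apertures sized to keep the Fresnel number high (the
  # closed forms' regime of validity: focal zone well separated from the
  # near field)
  cases <- list(list(fnum = 1.5, n_el = 65L), list(fnum = 4, n_el = 165L))
  for (cs in cases) {
    geom <- array_geometry(n_elements = cs$n_el, pitch = 0.3e-3)
    z_f <- cs$fnum * geom$aperture_width
    focus <- c(0, z_f)
    txd <- focus_delays(geom, focus)
    wave <- make_tone_burst(pulse_spec(5e6, 160, "therapy"), geom$fs)
    lam <- geom$wavelength
    bw_t <- 0.886 * lam * cs$fnum
    dof_t <- 7.1 * lam * cs$fnum^2
    lat <- image_grid(seq(-2.5 * bw_t, 2.5 * bw_t, by = bw_t / 25),
                      z_f + c(-1, 0, 1) * 1e-4)
    axi <- image_grid(c(-bw_t / 25, 0, bw_t / 25),
                      seq(z_f - 2.2 * dof_t, z_f + 2.2 * dof_t,
                          by = dof_t / 50))
    bw <- measure_beam_metrics(
      simulate_incident_intensity(geom, txd, wave, lat), focus)$beamwidth
    dof <- measure_beam_metrics(
      simulate_incident_intensity(geom, txd, wave, axi), focus)$dof
    expect_lt(abs(bw - bw_t) / bw_t, 0.15)
    expect_lt(abs(dof - dof_t) / dof_t, 0.25)
  }
})
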