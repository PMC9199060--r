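# fusbeam

Therapy planning, low-intensity focused ultrasound (FUS) delivery
scheduling, and real-time-style beam monitoring for a single diagnostic
linear imaging array — exercised end to end on a bundled linear
point-scatterer RF simulator instead of hardware.

## Who this is for

Low-intensity FUS therapies (microbubble-mediated radiosensitization,
blood–brain-barrier opening, neuromodulation) need three things: a plan
that tiles the treatment region with focal points, a source that steers
the beam through them, and live confirmation that the beam is where it
should be. An ordinary imaging array can do all three — it steers
electronically, and the backscatter of a short focused pulse carries an
image of the beam itself. `fusbeam` is a research implementation of that
system for people developing or evaluating ultrasound-guided FUS
pipelines: planning, sequencing, beamforming, and beam-field
reconstruction are all plain R (with a small C++ core), and a simulator
replaces the scanner so everything is testable.

## The method in brief

**Planning.** A closed polygon ROI on the image is tiled from closed-form
focal-zone estimates for a rectangular CW source,

    R_-3dB  = 0.886 * lambda * f#        (beamwidth)
    DOF_-3dB = 7.1  * lambda * f#^2      (depth of field)

with grid steps `dx = R_-3dB`, `dz = 0.5 * DOF_-3dB`, odd rows offset by
`dx/2`, and candidates outside the ROI discarded. `f#` is the ROI
center depth over the array aperture width.

**Monitoring.** For each focal point the array fires a 2-cycle focused
visualization pulse (same focal law as the 160-cycle therapy burst) and
beamforms the backscatter with delay-and-sum + dynamic receive focusing
(receive f# = 1, Hann apodization) weighted by the generalized coherence
factor (GCF, M = 2):

    y[x,z] = GCF[x,z] * sum_i w[i] * s_[x,z][i]

A plane-wave-compounded B-mode (11 angles, ±18°) smoothed over
5.5λ × 7λ supplies an echogenicity normalization `B_max / B[x,z]`
(identity where B is ≥60 dB under B_max), and a sliding pulse intensity
integral over the transmit pulse length L turns the normalized RF image
into the beam's intensity field, displayed in dB over the B-mode.

**Sequencing.** Each focal point gets a 50 ms treatment window (160-cycle
bursts at 3 kHz PRF) followed by a 2 s imaging window
(visualization + B-mode), then the beam moves to the next point;
per-point fields are max-normalized and averaged into a whole-session
coverage map.

## Worked example

```r
library(fusbeam)

geom <- array_geometry()          # 128 el, 0.3 mm pitch, 5 MHz, fs 20 MHz
roi  <- roi_polygon(rbind(c(-1e-3, 19.6e-3), c(1e-3, 19.6e-3),
                          c(1e-3, 20.4e-3), c(-1e-3, 20.4e-3)))
plan <- plan_therapy(roi, geom)
plan$grid
#> <fus_focal_grid> 42 focal points in 3 rows (dx 0.143 mm, dz 0.301 mm)
round(plan$f_number, 3)
#> [1] 0.525

phantom <- make_phantom("speckle",
                        list(x_range = c(-5e-3, 5e-3),
                             z_range = c(14e-3, 26e-3)), rng_seed = 1,
                        geom = geom)
sess <- run_mock_session(phantom, geom, plan$grid, therapy_config(),
                         seed = 1,
                         image_grid = default_grid(geom, c(17e-3, 23e-3),
                                                   c(-3e-3, 3e-3)))
sess
#> <fus_session> 42 focal points, 126 events, 86.1 s simulated (complete)
ig <- sess$image_grid
inroi <- outer(ig$z_axis, ig$x_axis,
               function(z, x) mapply(function(xx, zz)
                 point_in_roi(c(xx, zz), roi), x, z))
mean((sess$averaged$db >= -20)[inroi])      # ROI coverage at -20 dB
#> [1] 1
plot(overlay(sess$echo_map, sess$averaged)) # beam coverage over B-mode
```

The 42 focal points come from tiling the 2 × 0.8 mm ROI at
`dx = 0.143 mm` / `dz = 0.301 mm` (f# ≈ 0.52 at 20 mm depth); the
session log holds one treat, one visualize and one B-mode event per
point (126 events, 42 × 2.05 s of simulated sequence time), and every
ROI pixel of the averaged reconstruction ends up within 20 dB of its
peak. The peak itself sits in the focal plateau a millimetre or two
axially off the ROI center — an inherent limit of backscatter beam
mapping on diffuse speckle discussed in the methods vignette.

A command-line interface wraps the same pipeline
(`simulate`, `plan`, `beamform`, `visualize`, `run-mock`,
`compare-excitations`):

```sh
Rscript inst/cli/fusbeam plan inst/extdata/roi_example.csv \
    --config inst/extdata/example_config.json --outdir out/
```

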