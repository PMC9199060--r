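---
title: "Planning and monitoring a low-intensity FUS therapy from backscatter: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning and monitoring a low-intensity FUS therapy from backscatter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fusbeam` implements a single-probe system for low-intensity focused
ultrasound (FUS) therapy: the same diagnostic linear array plans the
treatment, delivers the (mock) therapy bursts, and monitors the beam in
near real time by reconstructing its intensity field from the
backscatter of a short visualization pulse. This vignette describes the
model behind each stage, the tunable parameters, what the bundled
simulator does and does not emulate, and the design decisions taken
where the problem was genuinely open.

## The therapy-planning model

The user supplies a closed polygon (the treatment region) drawn on a
B-mode image. Planning proceeds from two closed-form estimates for a
rectangular focusing source driven by a continuous wave:

$$R_{-3dB} = 0.886\,\lambda f_\#, \qquad DOF_{-3dB} = 7.1\,\lambda f_\#^2,$$

the $-3$ dB beamwidth and depth of field at wavelength $\lambda$ and
f-number $f_\#$. The f-number is the depth of the region's center over
the lateral aperture width $(n-1)\cdot\mathrm{pitch}$ (38.1 mm for the
default 128-element, 0.3 mm-pitch probe). The focal grid fills the
region's axis-aligned bounding box with lateral step
$\Delta x = R_{-3dB}$ and axial step $\Delta z = 0.5\,DOF_{-3dB}$; every
other row is shifted by $0.5\,\Delta x$ to reduce focal-zone overlap
between rows, and candidates outside the polygon are discarded.

Two readings were open and are fixed here: the "center point" of the
region is the bounding-box center (the rest of the construction is
bounding-box based, so this is the consistent choice; a polygon centroid
differs only for very asymmetric regions), and grid coordinates stay
*continuous* — the hardware implementation rounded candidates to a
display pixel lattice, which made its spacing slightly irregular, an
artifact we deliberately do not replicate. Boundary-touching candidates
are kept (containment is inclusive, with a $10^{-9}$ m tie tolerance at
the far box edge).

## Beam monitoring from backscatter

During each 2 s imaging window the array fires a 2-cycle focused
visualization pulse at the current therapy focus, records per-channel RF
at four samples per wavelength, and reconstructs:

1. **DAS with dynamic receive focusing.** Per pixel $(x, z)$ and channel
   at $x_e$, the two-way delay is
   $\tau = \tau_F[x_c] + (z + \sqrt{z^2 + (x - x_e)^2})/c$, where
   $\tau_F[x_c]$ is the transmit delay of the receive subaperture's
   center element. On the beam axis this is exactly the virtual-source
   law (the transmit leg approximated by the focal wavefront's transit),
   so echoes from the focus sum coherently. The receive aperture has a
   constant f-number of 1 (width $z$, centered on the element nearest
   the pixel, clipped at the array edges) and Hann apodization.
2. **Generalized coherence factor.** With $S[k]$ the length-$N$ DFT of
   the delayed subaperture samples,
   $GCF = \sum_{|k| \le M}|S[k]|^2 / (N\sum_k |s[k]|^2)$ with $M = 2$:
   the fraction of aperture-spectrum energy near DC. Coherent mainlobe
   pixels score near 1, off-axis clutter is suppressed. With very small
   edge subapertures $M$ is capped at $\lfloor (N-1)/2 \rfloor$ so
   wrapped DFT bins are never double-counted; $N = 1$ scores 1 by
   convention.
3. **Echogenicity normalization.** A co-registered plane-wave compounded
   B-mode (11 angles, $-18°..18°$, coherent sum, analytic-signal
   envelope along depth) is smoothed with a 5.5$\lambda$ × 7$\lambda$
   moving average; the beamformed image is multiplied by
   $\lambda_{norm} = B_{max}/B$ so the reconstruction reads as incident
   beam intensity rather than local scattering strength. Pixels whose
   smoothed envelope sits 60 dB or more under $B_{max}$ are treated as
   noise and get factor 1 (identity, not zero): dropout in anechoic
   regions then emerges from the low backscatter itself rather than
   being painted in.
4. **Pulse intensity integral.**
   $I[x,z] = \sum_{i=0}^{L-1} \Delta z_s |y_{norm}[x, z+i]|^2$ with $L$
   the transmit pulse length in samples and $\Delta z_s = c/(2 f_s)$ the
   axial sample period (distinct from the planning step $\Delta z$ —
   the source material overloads the symbol). The window looks *deeper*
   only, which cancels the half-pulse-deep bias of the RF image of a
   scatterer; point targets reconstruct to within a few micrometres of
   their true depth. The field is displayed in dB normalized to its
   maximum, overlaid (10 dB dynamic range by default) on the B-mode
   (60 dB range).

Session-level products average the per-point fields *after* per-frame
max-normalization (each displayed frame is self-normalized; averaging
linear, un-normalized frames would let bright-region frames dominate).

## What the simulator emulates — and what it does not

The bundled simulator is a linear, single-scattering, homogeneous-medium
model: each transmit element launches the delayed excitation with
spherical spreading $g(r) = 1/\max(r, \lambda)$ and a strip-element
directivity $\mathrm{sinc}(w\sin\theta/\lambda)\cos\theta$ with
$w = \mathrm{pitch}$; each point scatterer re-radiates the superposed
incident trace; receivers apply the same spreading and directivity. A
scatterer's reflectivity is a zero-mean fluctuation: phantoms store a
nonnegative amplitude magnitude and a ±1 polarity. Both choices were
forced by measurement, not taste: with omnidirectional elements the
integrated sidelobe clutter of wideband DAS sits near 0 dB and a 2:1
echogenicity step images as 1:1, and with all-positive reflectivities
the coherent bulk of dense speckle puts ~80% of channel energy below
1 MHz and buries the image. Neither pathology exists in the physical
system being modeled, so the simulator includes the minimal physics
(finite element width, zero-mean reflectivity) that removes them.

Delays are applied by linear interpolation on an internally oversampled
(4×, i.e. 16 samples/wavelength) band-limited copy of the waveform;
straight linear interpolation at 4 samples/wavelength attenuates
fractional-delay sums by up to 3 dB and measurably distorts the beam
(the focused beamwidth came out 35% too narrow before this fix). The RF
record the *beamformer* sees is still sampled at $f_s = 4 f_0$, like the
acquisition hardware.

Not modeled: frequency-dependent attenuation, nonlinear propagation and
harmonics (all processing is fundamental-band), bubble resonance
dynamics (microbubbles are strong linear scatterers with ~10× amplitude),
elevational geometry, element impulse responses, and electronic noise
unless `noise_sd > 0` is requested. A green test therefore establishes
the correctness of the *processing chain* on a faithful linear scene; it
does not establish in-vivo image quality.

Speckle phantoms place ~12 scatterers per resolution cell (beamwidth ×
half pulse extent) — above the ~10 needed for fully developed speckle,
small enough to keep full mock sessions inside a single-CPU test budget.
The B-mode inside `run_mock_session()` is computed once per session and
reused at every imaging window: the phantom is static, so every window's
compounded image is identical (with `noise_sd > 0` this trades one noise
realization for per-window ones; the event log still records each
window).

The plane-wave B-mode pulse is a Hann-tapered 3-cycle burst by default.
The source sequence fixes the visualization pulse (rectangular, 2
cycles) but never states the B-mode imaging pulse; an untapered 2-cycle
burst leaves the compounded point response's diagonal ridge artifacts
~15 dB higher (measured), which noticeably corrupts the echogenicity
map. Both pulse and taper are configurable.

## Numerical choices

* Fractional delays: linear interpolation everywhere (beamformer at
  $f_s$, simulator at $4 f_s$); out-of-record times contribute 0.
* Envelope: magnitude of the analytic signal along depth (FFT Hilbert).
* Hann windows regenerate per subaperture length; lengths ≤ 2 fall back
  to rectangular (the symmetric window degenerates to zeros there).
* Beam metrics interpolate the half-maximum crossings linearly between
  grid samples and are scale-invariant; the depth-of-field takes the
  contiguous above-half interval containing the peak.
* Aperture element selection rounds half-pixel ties up, identically in
  the compiled and reference beamformers.
* All randomness flows through explicit integer seeds; equal seeds give
  bit-identical phantoms, channel data, and session outputs.

## Known limitations

* **Axial plateau of speckle reconstructions.** Along the beam axis the
  visualization pulse stays coherent with the converging/diverging
  wavefront, so on diffuse speckle the reconstruction falls off axially
  much more slowly than the true incident intensity (a few dB over
  ±1–2 mm at $f_\# \approx 0.65$). Single-frame peak localization on
  speckle is therefore focal-zone-accurate, not wavelength-accurate;
  across ≥10 speckle seeds the seed-averaged field localizes the focus
  to well within a wavelength.
* **Out-of-region spill at −20 dB.** The −20 dB footprint of a focused
  beam at $f_\# \sim 0.7$ includes its transmit cone and a long axial
  corridor. For a treatment region a few millimetres tall, *even the
  ground-truth incident fields*, averaged over the focal grid, put the
  majority of surrounding pixels above −20 dB; the corresponding
  acceptance check is left red deliberately, with the reconstruction
  shown to spill no more than the ideal field does. At the 10 dB
  display range used for overlays, energy outside the region is minimal.
* Echogenicity normalization is a partial correction (different transmit
  focusing between the B-mode and visualization paths), which is why the
  two-region equalization is asserted as a ≥50% reduction of the log
  intensity ratio, not exact equality — in practice it achieves ~99% on
  the bundled phantom.
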