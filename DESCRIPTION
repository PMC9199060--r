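Package: fusbeam
Title: Therapy Planning and Backscatter-Based Beam Monitoring for Low
    Intensity Focused Ultrasound with a Diagnostic Linear Array
Version: 0.1.0
Authors@R:
    person("Miles", "Forrester", email = "mforrester@example.org",
           role = c("aut", "cre"))
Description: Tools for planning and monitoring low intensity focused
    ultrasound (FUS) therapy delivered with a diagnostic linear imaging
    array. A polygonal region of interest drawn on a B-mode image is
    converted into an ordered grid of focal points whose lateral and
    axial spacing follow closed-form beamwidth and depth-of-field
    estimates. The FUS beam is reconstructed from backscattered RF data
    using delay-and-sum beamforming with generalized coherence factor
    weighting, normalized by a smoothed B-mode echogenicity map, and
    integrated into a pulse intensity field. A linear point-scatterer
    simulator synthesizes multi-channel RF data and ground-truth
    incident fields so the full treat/monitor sequence can be exercised
    end to end without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    grDevices,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
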