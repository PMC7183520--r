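Package: petlm
Title: Listmode Simulation and NEMA NU 2-2018 Analysis for Digital Photon Counting PET
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Desk-scale listmode simulator for a silicon-photomultiplier PET
    ring with 1:1 crystal coupling, together with the NEMA NU 2-2018 listmode
    analysis suite. Builds the four-level detector hierarchy (modules, stacks,
    dice, crystals), generates labelled raw singles from phenomenological
    virtual experiments (scatter-phantom line source, sleeved sensitivity
    source, point sources), runs a digitizer chain (background noise, energy
    and timing blur, detection efficiency, pile-up, paralyzable deadtime,
    energy window), sorts prompt and delayed coincidences with a
    multiple-window takeAllGoods policy, and analyses the resulting listmode
    data: count rates, NECR and scatter fraction; TOF and energy resolution
    with per-LOR timing-offset correction; sensitivity with zero-attenuation
    extrapolation; and pre-reconstruction intrinsic spatial resolution by
    orthogonal projection of the source onto arc-corrected lines of response.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
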