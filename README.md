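# petlm

Listmode simulation and NEMA NU 2-2018 analysis for a digital photon
counting (SiPM, 1:1-coupled) PET ring.

PET performance evaluation is increasingly done directly on **listmode
data** — the raw stream of coincidence records — so that results do not
depend on a reconstruction algorithm. `petlm` provides, in one R package,
everything needed to exercise and validate that workflow at desk scale:

* a **scanner geometry** of 23 040 LYSO crystals (18 modules × 4×5
  stacks × 4×4 dice × 2×2 crystals of 4×4×19 mm) on a 764 mm-ID ring
  with a 164 mm axial FOV, with crystal-index ↔ position ↔ sinogram
  conversions and arc correction;
* a **phenomenological virtual-experiment generator** emulating the NEMA
  acquisitions (scatter-phantom line source, sleeved sensitivity source,
  point sources) with ¹⁸F decay, positron range, acollinearity,
  single-Compton phantom scatter, and exact ground-truth labels;
* a **digitizer chain** — background noise (461 kcps), energy blur
  (11.2% FWHM @ 511 keV), detection efficiency (86.5%), timing blur
  (220 ps FWHM), pile-up and paralyzable deadtime (5.9 ns), energy
  window (449.68–613.20 keV);
* a **coincidence sorter** (multiple-window, takeAllGoods, 2.0115 ns
  window, 100 ns delayed window, module-sector constraint) producing
  listmode datasets with a text and a bit-exact binary dialect;
* the **NEMA analyses**: count rates / NECR / scatter fraction, TOF and
  energy resolution with per-LOR timing-offset correction, sensitivity
  with zero-attenuation extrapolation and axial profiles, and a
  pre-reconstruction **intrinsic spatial resolution** method that
  orthogonally projects the source onto each arc-corrected LOR and reads
  per-axis FWHMs from the projected-distance histograms (including
  source localization by minimising the mean source-to-LOR distance).

The core quantities, in standard notation: `NECR = C_t²/C_tot` per unit
time and `SF = C_sc/(C_t + C_sc)` with `C_tot = C_t + C_sc + C_r`;
paralyzable deadtime inversion `τ = −ln(S_out/S_in)/S_in`; Compton
energy `E' = 511/(2 − cosθ)` keV; and the NEMA FWHM estimator (parabolic
peak through the top three bins, linearly interpolated half-maximum
crossings).

## Worked example

Simulate a point source at (0, 1, 0) cm for 1 s, then analyse the
listmode dataset:

```r
library(petlm)
g <- scanner_geometry()
cfg <- list(seed = 42,
            generator = list(preset = "point_source",
                             params = list(activity_bq = 2e6, duration_s = 1,
                                           position_mm = c(0, 10, 0))))
ds <- run_acquisition(cfg, g)
ds
#> listmode_dataset: 310645 records (308434 prompts, 2211 delayeds), duration 1 s

tof_resolution(ds, g, source_spec("point", c(0, 10, 0)), background = "none")$fwhm_ps
#> 307.3          # ps: two 220 ps singles blurs give sqrt(2)*220 = 311 ps
energy_resolution(ds)$fwhm_percent
#> 11.23          # % at 511 keV, the configured crystal resolution
res <- intrinsic_resolution(ds, g)   # source located from the data
res
#> intrinsic resolution (n = 306087): FWHM X 1.27 mm, Y 1.14 mm, Z 1.98 mm
res$source_position
#> (0.00, 10.11, 0.00) mm
```

The TOF and energy readouts recover the digitizer settings; the
intrinsic resolution shows the characteristic ring-scanner pattern
(axial FWHM worse than transverse, because few azimuthal angles reach
steep axial incidence), and the source is located to ~0.1 mm. A full
26 + 5 + 5 acquisition campaign at reduced statistics is available via
`run_experiment(demo_manifest(), "out/")`, and a thin CLI wrapper
(`inst/cli/petlm`) exposes `simulate`, `geometry dump`, and
`analyze countrates|tof|sensitivity|resolution`.

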