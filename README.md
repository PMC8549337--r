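# fidvol — simulation and volumetry of injectable liquid fiducial markers in CT

After resection of a head-and-neck tumour and free-flap reconstruction, the
tumour bed is nearly indistinguishable from the transplanted tissue in
postoperative CT. Injectable iodinated liquid fiducial markers (a sucrose
acetoisobutyrate carrier with an iodinated ester) let the surgeon mark the
resection surface with 10–30 µl droplets that appear as hyperdense
structures in CT. `fidvol` is an R package for radiologists, radiation
oncologists and imaging scientists who want to study — computationally,
with a reproducible digital phantom — how such low-dose markers behave
across tube voltages and in dual-energy CT:

* **Phantom + forward model.** Layered soft-tissue/flap/bone scenes with
  rounded (10 µl) or multilobular (20–30 µl) iodine deposits; acquisition as
  `HU = blur(material HU + c·s(kV), FWHM) + N(0, σ)`, where the iodine
  contrast `s(kV)` falls strictly with tube voltage (k-edge effect) and the
  Gaussian PSF produces partial-volume "blooming".
* **Threshold volumetry.** The two-step procedure: an automated surrogate
  for the visual lower-window setting, then segmentation of each marker as
  the 3D connected component ≥ 140 HU inside a spherical ROI; volume =
  voxel count × voxel volume (1 mm³ ≡ 1 µl).
* **Group statistics.** Per (injected volume, kV) group: mean, sample SD,
  the *norm interval* mean ± 1.96·SD, the segmented/injected ratio, and
  paired t-tests across kV settings.
* **Discriminability.** For 10 vs 30 µl groups: the observed gap
  Δ = min(V₃₀) − max(V₁₀), the border line
  B = (mean₃₀ − 1.96·SD₃₀) − Δ/2, and the normal-model separation
  probability Φ((B − mean₁₀)/SD₁₀), with reliability declared above 95%.
* **Dual-energy analysis.** Mixed-energy image (0.6·A + 0.4·B),
  two-material decomposition into a virtual non-contrast (VNC) image and an
  iodine map, and classification of hyperdense objects as iodine markers vs
  titanium clips / calcifications by VNC retention.

## Worked example

Simulate a mandible-segment-style phantom with three markers, acquire it at
120 kV and segment the 10 µl marker from its injection site:

```r
library(fidvol)

sc  <- build_scene(scene_config(lapply(c(10, 20, 30), marker_spec), seed = 7))
vol <- acquire_ct(sc, default_protocols()[["120"]], seed = 11)
segment_marker(vol, unlist(sc$markers[1, c("x", "y", "z")]))
#> <segmented_marker> 19.68 ul (205 voxels), peak 551 HU, centroid (8.2, 7.9, 9.1) mm
```

The 10 µl deposit segments to 19.68 µl: the point-spread function inflates
small high-contrast objects (blooming), and the effect grows at lower kV
where iodine contrast is higher. The full preclinical replication — 75
markers over 9 segments, each scanned at 70/100/120 kV:

```r
run_preclinical(preclinical_config(seed = 1))
#> <run_report> mode: preclinical
#>   225 measurements, 9 summary rows
#>  injected_ul  kv  n mean_ul sd_ul norm_lower norm_upper ratio
#>           10  70 25   25.85  0.35      25.17      26.54   2.6
#>           10 100 25   21.09  0.49      20.12      22.06   2.1
#>           10 120 25   19.17  0.36      18.47      19.87   1.9
#>           20  70 25   46.62  0.71      45.23      48.00   2.3
#>           20 100 25   39.48  0.71      38.09      40.88   2.0
#>           20 120 25   36.20  0.72      34.79      37.60   1.8
#>           30  70 25   65.33  0.86      63.66      67.01   2.2
#>           30 100 25   56.63  0.73      55.20      58.05   1.9
#>           30 120 25   52.53  0.62      51.30      53.75   1.8
#>   discriminability (smallest vs largest injected volume):
#>     70 kV: Delta 37.54 ul, border 44.89 ul, separation 100.00% -> reliable
#>     100 kV: Delta 33.31 ul, border 38.55 ul, separation 100.00% -> reliable
#>     120 kV: Delta 31.20 ul, border 35.70 ul, separation 100.00% -> reliable
#>   visibility: 225/225 markers (100%)
```

Reading the report: mean segmented volume falls strictly with kV for every
injected volume (the negative kV correlation), the segmented/injected ratio
is larger for 10 µl than for 30 µl at equal kV (relative blooming), and the
10-vs-30 µl separation probability exceeds 95% at all three voltages, so the
two injection volumes are reliably differentiable. Published group
statistics from the ex-vivo evaluation are shipped as reference data
(`reference_volume_summaries()`) for interval and ratio arithmetic, e.g.
`volume_summary(67.48, 7.33, 25, 10, 120)$norm_interval` gives
`53.1132 81.8468`.

A command-line front end over the same functions lives at
`inst/cli/fidvol.R` with subcommands `simulate`, `segment`, `analyze`,
`dect`, `replicate-preclinical` and `replicate-clinical`; volumes are
NIfTI-1, configs YAML, tables CSV, and every subcommand is deterministic
under `--seed`.

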