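---
title: "Simulating and quantifying low-dose liquid fiducial markers in CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and quantifying low-dose liquid fiducial markers in CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fidvol)
```

## The problem

After resection of a head-and-neck tumour with free-flap reconstruction, the
former tumour bed is nearly invisible in postoperative CT: native and
transplanted soft tissue have almost identical attenuation. Injectable
iodinated liquid fiducial markers (a sucrose-acetoisobutyrate carrier with an
iodinated ester) solve this by letting the surgeon deposit tiny (10-30 ul)
radiopaque droplets along the resection surface. Their usefulness hinges on
quantitative questions this package addresses computationally:

* Are 10 ul deposits visible at every tube voltage used clinically
  (70-120 kV), given that iodine contrast falls with kV?
* Can a 30 ul "attention" marker be reliably told apart from the 10 ul
  "basis" markers by its segmented volume?
* Can dual-energy CT distinguish iodine markers from titanium clips and
  calcifications that look identical in a single-energy image?

Raw per-marker scans from the ex-vivo evaluation of these questions were
never published — only group summary statistics and clinical counts. The
package therefore pairs the analysis chain (segmentation, statistics,
discriminability, dual-energy decomposition) with a synthetic phantom and CT
forward model, so every pipeline stage can be exercised and tested end to
end, and the published arithmetic can be recomputed from the printed
summaries.

## The phantom and forward model

A `phantom_scene` is a voxel grid (default 0.4 x 0.4 x 0.6 mm; only the
0.6 mm slice thickness is a reported acquisition parameter, the in-plane
pitch is a typical head-protocol value) with two fields: an integer material
label per voxel and an iodine concentration (mg/ml), positive only inside
marker deposits. The layered geometry emulates the ex-vivo preparation: a
flat soft-tissue block, covered by a muscle flap (the reconstruction
analogue), air above, and optionally a bone slab with two teeth at depth.
Markers are placed on a regular grid (default pitch 10 mm, mirroring the
uniform injection pattern) at 1-2 mm below the tissue surface.

Marker morphology follows the observed dichotomy: 10 ul deposits are
rasterised as single near-spherical lobes, larger ones as unions of 2-4
overlapping ellipsoidal lobes with seeded jitter in lobe centres and axes.
A bisection calibration rescales each deposit until its rasterised volume
matches the nominal volume within 2% (5% is the hard error limit), so the
geometric ground truth is exact by construction. The lobe jitter is also the
mechanism giving 30 ul groups their larger variance of segmented volumes.

Acquisition is a deliberately transparent three-step forward model:

1. **Lookup.** Each voxel gets the HU of its material at the protocol
   energy, plus `concentration x iodine_hu_per_unit`. The default iodine
   contrast (38/34/26/22/12 HU per mg/ml at 70/80/100/120/tin-filtered
   150 kV) decreases strictly with energy, modelling the loss of k-edge
   contrast. The default marker concentration (25 mg/ml relative units)
   keeps the noise-free marker peak at 600 HU even at 120 kV — far above the
   140 HU segmentation threshold, as observed. Absolute marker HU was never
   reported, so only these ordering relations carry meaning.
2. **Blur.** A separable isotropic Gaussian point-spread function (default
   FWHM 1.2 mm) stands in for the scanner's reconstruction kernel. This is
   the single mechanism producing "blooming": segmented volumes several-fold
   larger than injected volumes, growing as kV falls (higher contrast pushes
   the 140 HU isosurface further out) and relatively larger for small
   deposits (surface-to-volume scaling). Beam hardening, streak artifacts
   and scanner-specific kernels are not modelled.
3. **Noise.** Additive Gaussian HU noise, with the preset kV/mAs coupling
   mapped to 4/6/8 HU SD at 70/100/120 kV (500/200/120 mAs) and 6 HU for
   both dual-energy tubes. Every acquisition takes an explicit integer seed
   and is bit-reproducible.

With the default FWHM the simulated segmented/injected ratios are around
2-3.5, smaller than the published 5.9-8.9 (a real reconstruction kernel
blurs more anisotropically and the real deposits spread in tissue); the
package asserts only the trends — monotone decline with kV, larger relative
blooming for 10 ul than for 30 ul — which the forward model reproduces
robustly, not the absolute ratios, which are not identifiable from the
published summaries.

## Two-step threshold segmentation

The analysis procedure mirrors manual volumetry on a reading workstation:

1. `suggest_lower_level()` automates "raise the lower window level until all
   soft tissue disappears": the smallest integer HU excluding at least 99.9%
   of background voxels. The background is located robustly (median +/- a
   MAD-based window) unless a mask is given. On default phantoms this is
   always well below 140 HU, consistent with 140 HU being a usable
   threshold at every kV.
2. `segment_marker()` applies the lower threshold (140 HU by default,
   inclusive: a voxel exactly at the level is counted) and extracts the 3D
   connected component containing a seed point, restricted to a spherical
   region of interest (default radius 8 mm — large enough for the biggest
   blurred 30 ul deposit, small enough never to touch a neighbour at 10 mm
   pitch). Volume is voxel count times voxel volume; 1 mm^3 is 1 ul exactly,
   and partial-volume voxels count fully, as in a segment-then-count
   workflow.

Connectivity is configurable (6/18/26); the default 26 reads "coherent
voxels" as any 3D adjacency. The flood fill is validated against an
independent scalar depth-first oracle on random grids for all three
connectivities, and threshold monotonicity (raising the level never grows a
marker) is asserted on acquired phantoms. `detect_markers()` is the
unseeded variant for the clinical-simulation mode, with an optional upper
volume bound that screens out large bony components.

## Group statistics and the discriminability statistic

Per (injected volume, kV) group, `summarize_volumes()` reports the mean,
sample SD (n - 1), the *norm interval* `mean +/- 1.96 SD` — the range
expected to contain 95% of observations under a normal model — and the
segmented/injected ratio. Values stay at full precision internally and are
rounded only for display (two decimals for volumes, one for ratios). Note
that the published table labels the norm interval a "95% CI"; numerically it
is mean +/- 1.96 SD, not a standard-error interval, and that is what the
package computes. One published bound (the 10 ul @ 70 kV upper limit) is
consistent with unrounded inputs only, and agrees with the printed mean/SD
to 0.05 ul rather than 0.02 ul; the tests carry that exception explicitly.

The kV comparison is a paired two-sided t-test by default: the design is
repeated-measures (the same 75 physical markers scanned at all three kV),
so within-marker differences are the natural unit. A Welch unpaired option
and a Bonferroni adjustment are exposed but off by default (the original
analysis reported raw pairwise p-values; which test it used is unstated).
Exact published p-values are not reproducible without raw data and are not
targeted.

Discriminability of two injection volumes chains three quantities:

* `Delta = min(large-group volumes) - max(small-group volumes)` — the
  observed gap; the sign convention makes `Delta > 0` mean non-overlapping
  ranges (the verbal definition leaves the sign ambiguous; this is the only
  reading consistent with a gap depicted between the groups).
* `border = lower norm limit of the large group - Delta / 2`.
* `separation_probability = pnorm((border - mean_small) / sd_small)` — under
  a normal model of the small group, the probability that a small-volume
  marker falls on the small side of the border. Differentiation is deemed
  reliable above 0.95. The verbal description ("probability above the
  border", yet reliability for values > 95%) is internally inconsistent if
  read literally; the package adopts the self-consistent small-side reading
  and reports the complementary tail alongside.

The closed form is tested against a seeded million-draw Monte-Carlo oracle.
A caution for users: with 25 observations per group, `Delta` depends on
sample extremes and is noisy, so the reliability verdict at the 95% cutoff
flips in a few percent of replicates even for well-separated groups
(a 20k-replicate simulation of Normal(90, 10) vs Normal(200, 35) groups
puts the reliable fraction at 95.0%).

## Dual-energy decomposition

The vendor VNC algorithm is proprietary, so the package implements the
textbook two-material alternative: per voxel, `HU_A = base + c i_A`,
`HU_B = base + c i_B` (a configurable non-iodine spectral offset defaults to
0, i.e. soft tissue), giving `c = max(0, (HU_A - HU_B) / (i_A - i_B))`, a
mixed image `0.6 A + 0.4 B`, and `VNC = mixed - c (0.6 i_A + 0.4 i_B)`.
With matched forward and inverse iodine vectors and no noise this inverts
the forward model exactly: marker voxels return to the soft-tissue baseline
(the "absent in VNC" sign), titanium — spectrally flat in the material
table — keeps its full attenuation, and a calcification, whose modest
spectral slope is partly absorbed as apparent iodine, retains most of it.
The decomposition vectors are configurable independently of the simulation
vectors so model mismatch can be studied, and an optional 3 mm boxcar slab
average reproduces thick-slab map reading (off by default).

`classify_hyperdense()` scores each object segmented on the mixed image by
its *VNC retention*: mean VNC HU above a 50 HU soft-tissue reference divided
by mean mixed HU above the same reference. Iodine markers score near 0,
clips and calcifications near 1; the default decision threshold of 0.3
("markedly reduced visibility") is an engineering choice — no quantitative
cutoff was ever published — and a tie at the threshold counts as iodine so
that the degenerate threshold 1.0 labels everything iodine. The iodine map
is reported per object but deliberately not used for the decision: bone and
metal can appear bright in iodine maps too, which is exactly why VNC
retention is the discriminator.

## End-to-end replications

`run_preclinical()` reproduces the full design: 75 markers (25 each of
10/20/30 ul) split 8-or-9 per segment over 9 segment phantoms, each segment
acquired at 70/100/120 kV, every marker segmented from its known injection
site — 225 volume measurements feeding the nine group summaries, nine paired
kV tests and three per-kV discriminability assessments:

```{r preclinical, eval = FALSE}
report <- run_preclinical(preclinical_config(seed = 1))
report
```

On the default phantom the run reproduces the qualitative headline results:
mean segmented volume falls strictly from 70 to 100 to 120 kV for every
injected volume, the segmented/injected ratio is larger for 10 ul than for
30 ul at equal kV, and 10 vs 30 ul separation probabilities exceed 95% at
all three voltages.

`run_clinical_sim()` emulates the clinical transfer: n injections (default
66, mostly 10 ul), each lost with a Bernoulli failure probability (default
0.15, chosen to bracket the observed 83-86% visibility; the published
explanations — flap manipulation, injection failure — suggest no more
specific mechanism), then unseeded detection on a simulated acquisition and,
in dual-energy mode, VNC-based classification of every detection with clip
and calcification confounders present. The default clinical scene is a
tumour-bed/flap region without the mandible slab; an upper detection bound
of 1000 ul screens out large bony components when bone is included. With
`image = FALSE` only the marker-loss stage runs (surviving markers count as
detected), the lightweight mode used for replicate studies of the
visibility rate; a full-imaging run recovers exactly the surviving markers
at default contrast settings, which the test suite asserts.

## Numerical choices and problem sizes

* Voxel indices are 1-based in R; world coordinates are mm from the grid
  origin corner, voxel centres at `(i - 0.5) * spacing`. Cells are
  half-open for point-to-voxel mapping.
* Gaussian blur kernels are truncated at 3 sigma with boundary
  renormalisation, so constant fields are preserved exactly at edges.
* Sub-seeds for segments, acquisitions and replicates are drawn with
  `sample.int()` from the single user seed, keeping everything below 2^31.
* The test suite and the acceptance script use the study-scale design (9
  segments, 225 measurements, ~0.4 M voxels per segment volume) directly;
  a full preclinical replication takes a few seconds on one CPU. Oracle
  comparisons use 100 random grids up to 16^3 (flood fill) and 10^6 draws
  (normal-model probability).

## Limitations

* The forward model is image-domain only: no projection physics, beam
  hardening, metal streaks or scanner kernels; the PSF width is the single
  resolution parameter, and simulated blooming ratios are consequently
  smaller than published ones (trends, not absolute ratios, are the tested
  quantities).
* Absolute marker HU and product iodine concentration are unconstrained by
  any published value; defaults guarantee the one implied fact (visibility
  above 140 HU at all kV).
* The phantom cannot reproduce the published per-group means/SDs de novo —
  those depend on unpublished raw scans; they enter only as printed inputs
  to interval/ratio arithmetic.
* Co-registration of dual-energy volumes is perfect by construction; no
  registration is implemented.
* Marker loss in the clinical simulation is a homogeneous Bernoulli model;
  volume-dependent failure is not modelled (the published counts do not
  resolve it).
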