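---
title: "Methods: 3D cyto-nuclear and nucleolar foci quantification with verified phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D cyto-nuclear and nucleolar foci quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleovol)
```

# The problem

High-content screens of cultured neurons image multi-channel confocal
z-stacks (a DAPI nuclear stain plus one or two marker channels) across many
wells and fields, and ask whether a genetic condition changes nuclear
volume, nucleolar size and number, or marker intensities in the nuclear,
nucleolar and cytoplasmic compartments. Commercial instrument software
performs the per-slice measurements; the 3D reconstruction, per-well
aggregation and statistics are usually re-implemented ad hoc and are hard
to audit because the raw images are rarely shared.

`nucleovol` reimplements that whole chain as tested, seedable code, and
pairs it with a synthetic phantom generator whose ground truth is known
exactly. The phantoms carry the published effect sizes of a tauopathy
high-content study (MAPT-mutant versus control neurons) as injected
multiplicative factors, so every stage — segmentation, linking, focus
registration, aggregation, testing, and ΔΔCt quantification — can be
verified end to end without any raw data.

# The imaging pipelines

## Per-slice nuclear segmentation

Each axial section of the DAPI channel is smoothed (Gaussian,
`smooth_sigma_px`, default 1 px; smoothing informs the boundary only),
thresholded (Otsu on the smoothed slice, or a fixed value), optionally
hole-filled and watershed-split, then components are gated by area
(`min_area_px2`–`max_area_px2`) and by mean raw intensity. 2D connectivity
is 8-connected — this must be fixed for the 3D oracle comparison below to
be well defined. Components touching the slice border are kept at slice
level and handled at the 3D stage, so tall nuclei clipped laterally are not
lost slice by slice.

## Nearest-neighbour z-linking

3D nuclei are assembled by greedy one-to-one matching of component
centroids between consecutive (or gap-bridged) slices:

* candidate pairs must lie within `max_link_dist_um` (default 2 µm,
  in-plane, physical units);
* pairs are taken in order of ascending centroid distance; ties break by
  larger 2D pixel overlap, then smaller slice label — so the partition is
  invariant to label permutation except as a final resort;
* unmatched components start new objects; objects spanning fewer than
  `min_slices` (default 2) are discarded; `max_z_gap` (default 1) missing
  slices may be bridged.

Splits and merges are deliberately not followed: the losing branch starts
a new object, which keeps the algorithm order-independent. Volumes obey the
identity `volume_um3 = voxel_count × pixel_size_xy² × z_step` exactly, and
per-channel integrated intensities are exact voxel sums. The acceptance
suite proves that, on well-separated phantoms, this slice-wise procedure
partitions foreground voxels *identically* to brute-force 26-connected 3D
component labelling (an independent code path, `label_3d_components()`).

Coordinates are 0-based voxel indices; the physical position of a voxel is
`(index + 0.5) × spacing` µm, and all link distances are computed in µm.

## Focus detection and registration

Nucleolar foci are detected per slice inside the nuclear masks with a blob
detector (difference-of-Gaussians by default, grayscale disk top-hat as an
alternative, scale `scale_px`). Seeds are thresholded at `n_sigma` (3)
robust MAD units of the response over the whole slice — the whole slice,
not the nuclear interior, because real blobs and their halos would inflate
an interior noise estimate. Each seed is then refined to its half-maximum
support above the host nucleus' nucleoplasmic median (nucleoplasm = nuclear
mask minus candidate foci); this recovers the true blob boundary from the
generous detector halo and splits touching foci of comparable brightness.
Final gates: area within `min/max_area_px2` and mean raw intensity at least
`brightness_factor` (default 2) times the nucleoplasmic median — a
per-nucleus reference, chosen for robustness to per-cell staining
variation rather than a global cutoff.

3D foci reuse the same linker with `min_slices = 1` and, by default, no
z-gap bridging (small objects stacked in z would otherwise fuse). Each
focus is registered to the unique nucleus whose 3D mask contains its
centroid voxel — a single unambiguous containment rule; unassigned foci
(centroid in background) are excluded from per-cell metrics.

## Cytoplasmic shell

The cytoplasmic compartment is approximated by an ellipsoidal 3D dilation
of the nuclear mask of physical width `shell_width_um` (default 1.5 µm;
kernel radii are rounded to voxels per axis, so anisotropic stacks dilate
correctly), minus all nuclear masks, clipped to the image.

## Per-cell and per-well outputs

`cyto_nuclear_pipeline()` and `foci_pipeline()` emit one row per nucleus:
volume, per-channel nuclear and cytoplasmic mean/integrated intensities,
focus count, mean 2D focus area (px² and µm² — the "mean pixel area"
metric), total 3D focus volume, and the nucleolar mean intensity, defined
here as the mean marker intensity over all assigned foci voxels of the
cell (the study reports the quantity but not its formula). Border-touching
nuclei are dropped by default (their volumes would be truncated).
`summarize_wells()` aggregates per well (mean/median/sd per metric), flags
— but never drops — wells below a minimum cell count. Both the per-cell
table and the per-well summary are first-class: the statistics layer can
run on either unit, and defaults to cells, matching legends that count
"cells analyzed per condition".

# The statistics layer

`choose_test()` reproduces the study's selection logic: Shapiro–Wilk on
each sample (either non-normal at α = 0.05 → two-sided Mann–Whitney U);
otherwise a Brown–Forsythe (median-centred Levene) variance check, written
by hand because no implementation is available in this environment, with
unequal variances falling back to Mann–Whitney (Welch's t is available by
configuration — the study only says variance homogeneity was "verified");
otherwise the unpaired two-tailed Student t-test. Shapiro–Wilk is undefined
above n = 5000, so larger samples are gated on a deterministic
evenly-spaced subsample of 5000 values. Mann–Whitney p-values are exact
for min(n) ≤ 8 without ties and use the tie- and continuity-corrected
normal approximation otherwise; the test suite checks the exact branch
against full enumeration of rank assignments. Bonferroni correction
multiplies by an explicit family size `m` (the study never defines its
family; `m` is therefore always an argument and is logged with every
result), and significance labels follow the printed convention with
inclusive boundaries (`* : p ≤ 0.05` … `**** : p ≤ 0.0001`).
`boxplot_summary()` uses linear-interpolation quartiles (type 7) and the
1.5 × IQR outlier rule.

# ΔΔCt quantification

Technical Ct replicates are averaged per (sample, gene) before
differencing — the standard Livak formulation, and what performing
statistics "on the ΔCt values" implies. Then per sample
ΔCt = Ct(target) − Ct(reference), ΔΔCt = mean ΔCt(condition) − mean
ΔCt(control), fold = 2^(−ΔΔCt), with amplification efficiency assumed
exactly 2 (no standard-curve correction is modelled). Fold changes are
computed from pooled condition means (computing per-sample folds and
averaging is possible but not the default; the study does not say which it
used). P-values come from the same gated test layer applied to the two
ΔCt samples. The secondary reference gene (RPS27) is used only for
validation: a result is flagged concordant when the primary and secondary
log2 folds agree within 0.5; the references are never averaged.

# The synthetic world

The generator renders what the analysis assumes, with every deviation from
real data stated:

* **Nuclei** are filled ellipsoids with volume-preserving random
  anisotropy (axis ratios ~0.8–1.2) — the study never describes cell
  geometry, and ellipsoids exercise segmentation without biasing toward
  spheres. Radii are truncated-normal (mean 4 µm, sd 0.25 µm; symmetric
  3-sd truncation keeps the mean exact). Cells sit in a monolayer with
  jittered mid-plane z and an in-plane exclusion distance (default 9 µm),
  placed by rejection sampling capped at 10,000 attempts — generation
  fails loudly, it never loops forever.
* **Foci** (1–4 per nucleus, radius mean 1 µm, sd 0.2 µm) are placed
  wholly inside their nucleus. Two resolvability rules are part of the
  stated world: focus radii are floored at 0.65 z-steps (smaller foci are
  axially sub-resolution and can fall entirely between slice centres), and
  focus pairs must either be separated in-plane by several pixels plus the
  blur halo or have enough axial clearance that an empty slice lies
  between them. Without these rules "count recovery" would be ill-posed at
  the stated voxel size, not a property of the algorithm.
* **Voxel calibration** defaults to 0.3 µm xy / 1.0 µm z (typical for a
  40× water-immersion confocal; the study names the objective but no voxel
  sizes).
* **Optics and noise**: isotropic Gaussian blur (σ 0.2 µm) followed by
  Poisson shot noise on the blurred signal plus additive Gaussian read
  noise (sd 2) — the standard fluorescence model; both switchable to zero
  for exact tests.
* **Intensities**: per-cell lognormal staining variability (CV ≈ 20%)
  multiplies nuclear and focus amplitudes, so condition ratios have
  realistic Monte-Carlo error. The foci-channel preset renders zero
  nucleoplasmic and extranuclear baseline — the nucleolar pool is the
  quantity of interest, and a nonzero diffuse pool would make the raw
  foci-voxel mean a biased estimator of the injected amplitude factor
  (the per-cell metric is deliberately *not* background-subtracted,
  because the study's is not).
* **Effects** are multiplicative per (condition, quantity): a
  nuclear-volume factor f scales radii by f^(1/3), a focus-area factor by
  sqrt(f), amplitude factors scale amplitudes directly. The control
  condition must carry factors of exactly 1. `preset_design()` encodes the
  study's printed percentages (e.g. SH-SY5Y 1 h P301S: nuclear volume
  ×1.025, nucleolar size ×1.10, nucleolar nP-Tau ×2.0; iPSC IVS10+16:
  nuclear volume ×1.45). The 48 h presets reuse the 1 h amplitude factors
  because the sustained increase is reported only as "similar".
* **qPCR**: Ct(sample, gene) = baseline − log2(true ratio) + N(0, sd) per
  technical replicate; reference genes are drift-free by construction.
  Biological replication (default 3 samples/condition, "≥ 3 independent
  experiments") enters only through this noise — no sample-level random
  effect is modelled. The `samples_per_condition` field was added so that
  per-sample ΔCt statistics are possible at all.

What a green test does **not** establish: performance on touching or
apoptotic nuclei, anisotropic PSFs, uneven illumination, autofluorescence,
mitotic figures, or real staining backgrounds. The phantoms are a
correctness oracle for the computation, not a realism benchmark; at the
default noise level the pipeline still occasionally splits a nucleus chain
or a focus (a percent-level artifact rate visible in the analysis scripts'
recovered-versus-planted counts), which is why recovery criteria are
stated as ratios with Monte-Carlo standard errors rather than exact counts
except on the clean suites.

# Numerical choices

* Otsu thresholds are computed on a 256-bin histogram; an all-constant
  slice yields an empty segmentation, not an error.
* Watershed splitting floods a 3-4 chamfer distance transform from markers
  taken at ≥ 60% of each component's distance maximum, with FIFO ordering
  so results are deterministic.
* Convolution uses replicate padding; kernels extend to 3σ.
* Greedy matching ties (equal distance and overlap) fall back to smaller
  labels — deterministic, and reached only for exactly symmetric
  geometry.
* Degenerate statistics inputs error loudly (n < 3 for the gate, p
  outside [0, 1], empty box-plot groups); zero-variance samples are routed
  to the nonparametric branch.
* Seeds: every field derives its own seed from the design seed (kept
  below 2^31), so plates are bit-reproducible and parallelisable.

# Known limitations

* The linker follows the one-to-one matching reading of "nearest-neighbour
  3D reconstruction"; instrument software details (Harmony's exact size and
  brightness cut-offs, its gap handling) are undisclosed, so defaults here
  are documented implementation choices, not reproduced values.
* Nucleolar size is reported both as mean 2D focus area (the iPSC metric)
  and as 3D focus volume; which one feeds the statistics is a
  configuration choice.
* No mixed-effects modelling of well/experiment nesting, and no FDR
  procedures — matching the study's analysis, not best current practice.
* TIFF I/O is out of scope in this build: stacks are in-memory arrays and
  all tabular outputs are CSV.
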