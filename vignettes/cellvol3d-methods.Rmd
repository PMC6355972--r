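---
title: "Measuring single-cell volume expansion and its osteogenic readouts in 3D hydrogel culture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring single-cell volume expansion and its osteogenic readouts in 3D hydrogel culture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellvol3d)
```

# The measurement problem

Mesenchymal stem cells (MSCs) encapsulated in alginate hydrogels expand
their volume as they spread, and the degree of expansion tracks their
commitment to the osteogenic lineage. Asking whether volume — rather
than shape, stiffness sensing, or matrix chemistry — drives
differentiation requires a battery of quantitative readouts around a
single biological axis:

* **3D morphometry** of single cells from membrane-dye confocal
  z-stacks: volume, surface area, and the sphericity index;
* **nuclear:cytoplasmic (N:C) localization** of transcription factors
  (RUNX2, YAP) from DAPI / phalloidin / target-protein images;
* **relative intracellular calcium** from the Fluo-3 / Fura-red
  ratiometric pair (a TRPV4-activity proxy);
* **peri-cellular matrix accumulation** of fluorescent alginate;
* **hydrogel mechanics**: initial elastic modulus and the
  stress-relaxation half-time that distinguishes fast- from
  slow-relaxing gels;
* **osmotic pressure calculators** for the PEG-400 concentrations used
  to confine or release cell volume;
* **population statistics**: ALP-positive fractions, rank-correlation
  trends, and the saturating volume-response curve.

This package implements each readout as a small, testable function, and
pairs them with a phantom generator that produces synthetic inputs with
*exact analytic ground truth*. Every pipeline stage can therefore be
validated quantitatively without access to microscope data.

# Conventions

All physical quantities cross API boundaries in **micrometres,
kilopascals and seconds**. Images live in an `ImageStack`: a 4D array
with dimension order `(y, x, z, channel)`, 1-based indices, and a named
voxel pitch `c(y=, x=, z=)` in µm. The voxel with index `(i, j, k)` has
its centre at `((i - 1/2) dy, (j - 1/2) dx, (k - 1/2) dz)`. The default
phantom spacing is 0.2 × 0.2 × 0.4 µm — the 0.4-µm z interval typical of
fixed-sample confocal acquisition — so anisotropy is exercised by
default rather than hidden behind isotropic test cases.

Stacks are stored as multi-page 32-bit float TIFF, intensities scaled
into [0, 1] with the scale factor recorded in a JSON sidecar together
with spacing and channel names. On read, spacing is resolved as:
explicit override → sidecar → OME-XML `PhysicalSize` attributes in the
TIFF description. A file with none of the three is an **error**; a
silently assumed default voxel size is the classic way to be wrong by
2× in volume.

# 3D morphometry

## Thresholding

Commercial packages determine a segmentation threshold automatically by
proprietary means. The open, automatic analog used here is **Otsu's
method** over the full stack histogram (256 bins): the threshold
minimizing within-class intensity variance. To probe how sensitive a
volume estimate is to this choice, `selectThreshold(method =
"otsu_plus_k_sd")` raises the baseline by `k` global intensity standard
deviations, and `thresholdSensitivity()` tabulates volume against `k`.
Because supra-threshold sets nest as the threshold rises — and per-slice
hole filling preserves nesting — measured volume is provably
non-increasing in `k`, which the test suite asserts on noisy phantoms.
Otsu is a stand-in for the unavailable proprietary optimizer, not a
claim of equivalence; the sensitivity scan is the antidote to that
uncertainty.

## Segmentation

Foreground components are labeled with **26-connectivity**:
membrane-dye images of cells with thin protrusions fragment under
6-connectivity, and a protrusion severed from its body corrupts both
volume and sphericity. Holes are filled per z-slice before labeling,
because membrane dyes label the cell surface more brightly than the
interior while voxel-count volume presumes solid objects. Components
below `minVolumeUm3` (default 65 µm³, a ~2.5-µm-radius sphere) are
discarded as debris — an explicit, configurable cut, since no
biologically meaningful cell is that small.

Quality-control flags implement the "single cells not in contact"
selection auditable-y: `touches_border` marks cells clipped by the
stack boundary; `touches_other_cell` marks both (a) distinct labels
within one voxel of each other and (b) single components that split
into two or more substantial parts under progressive erosion — the
signature of two cells merged through a contact neck. Flagged cells are
*kept* in the output with their flags; exclusion happens downstream
where it can be audited, never silently inside the segmenter.

## Volume, area, sphericity

Volume is voxel counting: `n × dy·dx·dz`. On a digitized r = 5 µm
sphere at 0.2 µm spacing this recovers the analytic 523.6 µm³ within
0.5%, and within 2% for radii down to 2.5 µm (the 1-µm nominal beads
used for validation in practice sit at the resolution limit; the
phantom suite covers 2.5–7.5 µm).

Surface area is **not** computed by counting exposed voxel faces: face
counting overestimates a sphere's area by ~50% (the staircase
artifact), which would drag the sphericity of a perfect sphere to
~0.67 and destroy the index's anchor. Instead the binary component is
lightly smoothed with a separable Gaussian (default SD of 1 voxel per
axis — just enough to suppress the voxel staircase without eroding
shape features larger than a voxel) and triangulated at the 0.5
iso-level by **marching tetrahedra** with anisotropic spacing; the area
is the triangle sum. On digitized test shapes this yields sphere areas
within ~0.5% (tolerance 3%), 10-µm cube areas within ~3.5% (tolerance
5%, the corner rounding from smoothing), and sphere sphericity ≥ 0.998.

Sphericity is
$$\Psi = \frac{\pi^{1/3}\,(6 V_c)^{2/3}}{A_c},$$
1 for a sphere, decreasing toward 0 for elongated shapes. A mesh
allowance of ±0.02 applies to digitized shapes. Validation uses exact
spheroid areas (prolate/oblate closed forms) so the ellipsoid
cross-check is analytic, not itself mesh-based. Note a 1:1:10 prolate
spheroid has Ψ ≈ 0.59 — sphericity falls toward 0 slowly; values below
0.5 already indicate extreme elongation.

## Protrusion phantom geometry

The protrusion phantom is a sphere of radius *R* with a capsule arm:
cylinder of radius *r* spanning `[R, R + L]` along +x, closed by
hemispherical caps at both ends. The inner cap fills the neck where the
cylinder meets the body — without it the arm would touch the body in a
single point and pinch off under digitization. The union volume is
exact:
$$V = \tfrac{4}{3}\pi R^3 + \pi r^2 L + \tfrac{2}{3}\pi r^3 +
\frac{\pi r^4}{4R},$$
the last term being the sliver of the inner cap that pokes outside the
body (it integrates to exactly π r⁴/4R for r ≤ R). Keeping the truth
analytic means the volume oracle never depends on a second voxelization.

# Localization (N:C ratio)

Compartments come from Otsu masks: nucleus from DAPI, cell from
phalloidin, cytoplasm = cell − nucleus, nucleus clipped to the cell.
The ratio is the **ratio of compartment mean intensities** — "average
over the nuclear area divided by average over the non-nuclear area" —
not a mean of per-pixel ratios, and there is no background subtraction
by default (an optional corner-region estimator exists for data that
need it). The ratio is invariant to positive rescaling of the protein
channel and independent of voxel-spacing metadata, both asserted as
properties. 2D analysis uses a single focal plane by default (the
mid-plane of a stack), with a mean projection behind a flag; on
radially symmetric phantoms the mid-plane and volumetric ratios agree
within 5%, and paired noisy phantoms reproduce the 2D/3D concordance
(r > 0.9 at n = 50, 5% noise) that justifies planar analysis in
practice.

# Ratiometric readouts

**Calcium**: per-cell mean Fluo-3 over mean Fura-red. This is a
relative measure — ratiometric pairs cancel dye-loading differences but
are not calibrated to molar concentration, so values are comparable
across conditions, not absolute. Cells whose Fura-red mean falls below
5 background SDs are flagged invalid rather than dropped: a silent drop
would bias any per-condition average.

**Matrix accumulation**: mean alginate intensity within 3 µm outside
the cell border over the mean in a 28–32 µm background shell. Distances
are Euclidean in physical units (exact distance transform, anisotropic
sampling). "Background at 30 µm" is a distance, not a region; the
measure-zero contour is widened to a ±2 µm shell so it contains pixels,
with the half-width configurable. The inner band is exterior-only:
whether cell-interior pixels belonged in the original band is
unknowable from the description, and excluding them is the declared
choice. Pixels of other segmented cells are excluded from the
background.

# Mechanics and osmotics

The **initial modulus** is the least-squares slope of stress vs strain
restricted to the 5–10% strain window, in kPa. The **relaxation
half-time** τ½ is the first time the hold-phase stress crosses half of
σ₀, located by linear interpolation between samples (grid-independent);
σ₀ is the stress at the first hold sample — "the initial stress reached
at the hold strain" — not the ramp peak. Records that never halve
(elastic, or a standard-linear-solid with plateau fraction ≥ 0.5)
report `NA` with the final stress fraction, never a fabricated time.
Synthetic traces use a linear-elastic ramp at 0.00833 s⁻¹ (1 mm/min on
a 2-mm sample) and Maxwell / SLS / elastic hold models with closed-form
half-times for validation.

**PEG-400 osmotic pressure** uses the empirical quartic
$$y(\mathrm{atm}) = 2\times10^{-5}c^4 - 7\times10^{-4}c^3 + 0.0311c^2 +
0.5596c$$
with coefficients verbatim at published precision (no refit), × 101.325
kPa/atm; osmolarity treats PEG 400 as a single 400 g/mol osmolyte
(25 c mOsm/L). Concentrations 1.5 / 3 / 6% reproduce 92 / 197 / 441 kPa
and 37.5 / 75 / 150 mOsm/L. Hypoosmotic dilution with water fraction
*w* scales osmolarity by 1 − *w*.

# Statistics

ALP positivity is summarized as a percentage with an exact
Clopper–Pearson interval. Rank correlations use mid-ranks; the p-value
is an exact full permutation enumeration for n ≤ 10 and the
t-approximation above that. The volume-response trend is fit either
linearly (OLS) or as the saturating form r = aV/(k + V)
(Levenberg–Marquardt, initialized at a = max(r), k = median(V)); which
functional form a dataset warrants is left to the analyst — both are
implemented and the choice is explicit, since the underlying nonlinear
form used historically is not documented. Group comparisons are the
standard two-sample t-test and one-way ANOVA with Bonferroni-adjusted
pairwise follow-ups.

# The phantom generator as study stand-in

No raw images from the motivating experiments are publicly deposited,
so the generator defines the study conditions this package is tested
under:

* **Geometry phantoms** (sphere, ellipsoid, protrusion, two-sphere
  contact) are voxelized by centre-inclusion with analytic volume/area
  truths, additive Gaussian intensity noise clipped at zero (Poisson
  available by option — the true noise statistics of the source imagery
  are unknown, so the default is declared, not inferred).
* **N:C phantoms** prescribe plateau intensities, so the true ratio is
  their quotient; default noise SD 5 on a cytoplasm of 100 (5%).
* **Accumulation phantoms** multiply a uniform gel background by a
  known fold in the 0–3 µm shell.
* **Relaxation traces** carry closed-form half-times.
* **The population phantom** draws per-cell volumes from lognormals in
  four condition arms — fast / mid / slow stress relaxation plus a
  hyperosmotically confined arm, with mean volumes 4500 / 2200 / 1100 /
  700 µm³ and CV ≈ 0.31, 75 cells each (300 total) — and scores ALP
  positivity as Bernoulli with the saturating link
  g(V) = 0.6·V/(2000 + V). The arm means span the volume range over
  which the ALP response curve is observed; the link amplitude (60%)
  and half-saturation volume (2000 µm³) match the scale of reported
  ALP percentages. With k = 0 the link degenerates to a flat null
  useful for bias checks.

What the phantoms deliberately do **not** model: the microscope
point-spread function, depth-dependent attenuation, bleaching, or
crowded multi-cell fields beyond the two-sphere contact case. Passing
the phantom suites therefore demonstrates that the *measurement
operators* are correct on known geometry at realistic noise — it does
not certify segmentation quality on low-contrast real imagery, which
always needs its own QC (the flags and the threshold-sensitivity scan
exist for exactly that purpose).

# Numerical choices

* Histogram Otsu uses 256 bins over the observed intensity range;
  the exhaustive variance scan agrees to within two bin widths.
* Surface meshing smooths with SD = 1 voxel per axis; smoothing is in
  voxel units because the staircase artifact lives in voxel space.
* The EDT is the exact lower-envelope algorithm with per-axis physical
  step sizes; no chamfer approximations.
* τ½ interpolation is linear in stress between bracketing samples; an
  exactly-at-target first sample yields τ½ relative to the hold start.
* The saturating fit's initialization (a = max(r), k = median(V)) is
  deterministic; non-convergence raises an error carrying the
  optimizer message rather than returning a half-converged object.
* Pipeline tables are written at 6 significant digits, making repeat
  runs byte-identical; per-stage seeds derive from the global seed as
  `(seed·1009 + offset(stage)) mod 2³¹−1` with fixed per-stage
  offsets, so stage insertion never reshuffles downstream randomness.
* Problem sizes in the validation suites (phantom radii 2.5–7.5 µm at
  0.2 µm pitch, 50-phantom Monte-Carlo recoveries, 300-cell
  populations) were chosen to bound digitization and sampling error
  well below the asserted tolerances while keeping the full suite
  runnable in minutes on a laptop.

# Known limitations

* One nucleus per cell is assumed; multi-nucleus masks are flagged and
  the largest component used.
* The erosion-split doublet detector is tuned for near-tangent
  contacts; deeply fused pairs (centre distance ≪ 2r) are genuinely
  ambiguous from a membrane channel alone.
* Surface area of components thinner than two voxels is reported with
  a warning; at that scale the mesh is dominated by discretization.
* The Fig-7a-style saturating curve fitted to *per-cell binary*
  outcomes is statistically unidentifiable to tight tolerances at
  n ≈ 300 (binomial noise); parameter-recovery validation therefore
  uses continuous responses at 5% noise, and population-level checks
  assert the rank trend, not the curve parameters.
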