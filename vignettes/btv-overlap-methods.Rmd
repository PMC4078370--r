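---
title: "Methods: spatial overlap of FDG-PET subvolumes across chemoradiotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial overlap of FDG-PET subvolumes across chemoradiotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petbtv)
```

## The question

Locally advanced pancreatic cancer is treated with chemoradiotherapy (CRT),
and local failure within the gross tumour volume (GTV) is common. Boosting
the radiotherapy dose to a *biological target volume* (BTV) — a subvolume
selected from functional imaging — is only sensible if the region that will
remain metabolically active after treatment can be identified *before*
treatment. This package implements the analysis that tests that premise:
segment the baseline FDG-PET tumour at 40% and 50% of its SUVmax, segment
the post-CRT residual uptake at 60–90% of the (lower) post-treatment SUVmax,
propagate the post-CRT contours onto the planning CT through a verified
deformation field, and quantify how much of each residual volume falls
inside each baseline volume.

## The statistic

For binary masks $A$ (baseline subvolume) and $B$ (residual volume) on a
common grid, the overlap fraction is

$$\mathrm{OF}(A \mid B) \;=\; 100 \times \frac{|A \cap B|}{|B|}\,,$$

with voxel-counting cardinalities. It is asymmetric by design: the residual
volume is the reference, so $\mathrm{OF} = 100$ means the residual is
entirely contained in the baseline subvolume — the ideal case for BTV
definition. Coverage of the GTV uses the same statistic with the GTV as
reference. Cohort rows are summarised by the arithmetic mean, extrema, and
the midpoint-convention median; the within-patient SUVmax change is tested
with a two-tailed paired $t$-test, $t = \bar d / (s_d/\sqrt{n})$ with
$n - 1$ degrees of freedom.

## Pipeline stages and their conventions

**SUV quantification.** Body-weight SUV:
$\mathrm{SUV} = c_{\text{act}}\,[\mathrm{Bq/ml}] \times w\,[\mathrm{g}] / D\,[\mathrm{Bq}]$,
assuming 1 g/ml tissue. No decay or uptake-time correction is applied beyond
what the scanner reconstruction already did; the uptake time is recorded as
provenance only. SUVmax is the single hottest voxel inside an axis-aligned
elliptical ROI (voxel-center inclusion test), with ties broken at the
smallest column-major linear index so results are deterministic.

**Segmentation.** A voxel enters a mask iff it lies in the ROI and its SUV
is *at or above* the threshold. The inclusive comparison makes
`fraction = 1` return exactly the peak voxel. By default only the
26-connected component containing the SUVmax voxel is kept: the analysis
concerns one tumour focus, and discarding disconnected islands (bowel or
renal uptake caught by the ROI) preserves the nesting guarantee
$f_1 > f_2 \Rightarrow M(f_1) \subseteq M(f_2)$, which in turn forces
volumes to be non-increasing in the threshold and
$\mathrm{OF}(\text{Pre40}\mid\cdot) \ge \mathrm{OF}(\text{Pre50}\mid\cdot)$.
The connectivity rule is a package choice, declared rather than inferred,
and can be switched off. An absolute-SUV mode (e.g. SUV 2.5) exists for
comparison; in the pancreas it is hard to separate tumour from adjacent
liver and bowel at such a threshold, which is why relative thresholds are
the default.

**Registration.** The commercial non-rigid algorithm used clinically is out
of scope; the pipeline instead *consumes* a deformation field with a
verifiable contract. Fields live on the fixed (planning) grid in pull-back
convention: the propagated value at planning point $x$ samples the moving
(post-CRT) image at $x + d(x)$. Masks are warped by trilinear resampling of
their 0/1 indicator and re-binarization at 0.5 — smoother volume behaviour
under shrinkage than nearest-neighbour, at the cost of needing the object
to span a few voxels. `validate_field()` checks invertibility via
finite-difference Jacobian determinants, and `rigid_align()` provides the
translation-only pre-alignment (normalized cross-correlation,
integer-voxel search then 1/2- and 1/4-voxel refinement; rotation is
omitted because patients are scanned immobilised in the treatment
position). Deterministic tie-breaks: smaller translation norm, then
lexicographic order.

## The phantom generator

Real paired scans are not redistributable, so the generator builds scan
pairs whose ground truth is known exactly:

- **Baseline**: a truncated 3-D Gaussian uptake profile inside an
  ellipsoidal GTV ($\sigma_i$ = half the GTV semi-axis $r_i$), scaled so
  the hottest voxel equals the requested peak. Gaussian profiles give
  analytic iso-surfaces, so the 40%-of-peak region is a computable
  ellipsoid — the oracle for segmentation tests.
- **Containment control**: the residual ellipsoid is placed on the line
  from the peak outward (first grid axis), its offset solved by bisection
  on the *voxel-counted* containment in the baseline 40% region, so the
  requested fraction is realised to well within a voxel shell. An
  unreachable request (residual larger than the 40% region) fails with the
  limiting axis named.
- **Response geometry**: the post-CRT anatomy is the planning-space pattern
  pushed through $\varphi(x) = c + s\,(x - c) + t\,e_3$ (uniform shrinkage
  $s$ about the tumour centre composed with a caudal shift $t$; third grid
  axis = cranio-caudal, increasing index = inferior). The image is sampled
  analytically at $\varphi^{-1}$, so no interpolation error enters the
  ground truth, and the returned field $d(x) = \varphi(x) - x$ is exact
  with Jacobian $s^3 > 0$.
- **Scanner effects**: separable Gaussian PSF blur (reflective boundaries,
  kernel cut at $4\sigma$) followed by additive zero-mean Gaussian noise in
  SUV units, clipped at zero. Additive noise on the reconstructed image —
  not Poisson noise in counts — is deliberate: the pipeline operates on
  reconstructed SUV images, and the blur already reproduces the effect the
  analysis cares about, namely the recovery-coefficient (partial-volume)
  depression of measured SUVmax in small residuals (measured post peak
  ≈ 3.0 for a true 3.6 at 6 mm FWHM).

Defaults are fixed study conditions, not tuning knobs: 64³ grid at 2.5 mm
(planning-CT slice thickness), GTV semi-axes (25, 22, 18) mm ≈ 41.4 cm³ and
residual semi-axes (14, 12, 10) mm ≈ 7.0 cm³ (the transcribed cohort's mean
GTV and mean Post60 volumes), baseline/post peaks 8.0/3.6 (the cohort
median SUVmax values), background SUV 1 (soft-tissue level), shrinkage 0.85
with a 5 mm caudal shift (the moving-tumour behaviour seen clinically),
PSF 6 mm FWHM (clinical whole-body PET), noise sd 0.2 SUV. The containment
fraction has no published per-patient truth; it is the generator's free
parameter, and its default 0.85 reflects the high containment the cohort's
overlap table implies.

What the phantom does **not** emulate: respiratory motion, attenuation and
reconstruction artefacts, heterogeneous (non-Gaussian) uptake textures,
non-affine deformations, and neighbouring avid organs. Passing phantom
tests therefore validates the *pipeline machinery* — segmentation,
propagation, counting — not the clinical claim itself, which rests on the
transcribed per-patient tables.

## Cohort fixtures and the analysis set

The per-patient tables are shipped as plain-text transcriptions, with the
original footnote symbols kept verbatim as missing-data codes. The
summary-statistics analysis set is the nine patients present in the overlap
table (1, 2, 4, 5, 7, 8, 14, 16, 17): this is the only set that reproduces
every printed mean and the GTV range 22.3–80.2 cm³. Eligibility filtering
uses five exclusion reasons applied in fixed order (complete metabolic
response, non-avid tumour, missing post-CRT scan, diffuse uptake, elevated
glucose), which accounts 4 + 1 + 1 + 1 + 1 = 8 exclusions and 9 inclusions.
The per-patient *assignment* of reasons to the excluded patients is not
derivable from the tables, so the flag fixture is labelled synthetic; only
its counts are meaningful. The printed medians of the SUVmax columns are
not reconstructible from the printed per-patient values under any inclusion
rule we tried, so no median is asserted anywhere; the package's median uses
the plain midpoint convention and says so.

## Numerical choices

- Percentages and volumes are kept at full precision internally and
  rounded half-away-from-zero to one decimal only in reports
  (`round_half_up()`), matching table formatting conventions.
- Summary reproduction passes at ±0.05, i.e. agreement of the printed
  one-decimal value.
- Field inversion is a fixed-point iteration with border-clamped sampling
  (tolerance 10⁻³ mm, cap 50 iterations); on smooth affine-like fields the
  warp–inverse-warp round trip recovers masks at Dice ≥ 99%.
- Degenerate inputs fail loudly: empty ROIs, non-avid images in relative
  mode, empty reference volumes, zero-variance differences in the t-test,
  constant images in rigid alignment.

## Problem sizes

The test suite runs most properties on a 40³ reduced phantom (18, 16, 14 mm
GTV) where geometry permits, and on the full 64³ phantom where resolution
matters: the 20-phantom nesting sweep, containment recovery at
ρ ∈ {0.25, 0.5, 0.75, 1}, the warp volume law, and the mask round-trip
(small masks flip a visible fraction of their boundary voxels under double
resampling, so that invariant is only meaningful for well-resolved
residuals). The scripted analyses under `analysis/` use 5 replicates per
containment level. These sizes were chosen as the smallest at which the
voxel-counting tolerances quoted above are comfortably resolved.

## Known limitations

- Translation-only rigid alignment; rotations and non-rigid optimisation
  are intentionally not implemented — the deformation field is an input.
- Axis-aligned ellipsoidal ROIs only.
- The overlap statistic is voxel-counting, with no partial-voxel weighting;
  sub-voxel surface effects are bounded by one voxel shell and the fixtures
  and phantoms are sized accordingly.
- Single-focus tumours: the component-keeping rule assumes one lesion.
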