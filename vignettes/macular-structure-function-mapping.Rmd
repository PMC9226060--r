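---
title: "Mapping macular structure–function correlations: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping macular structure–function correlations: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macumap)
```

This vignette is the package's account of the science it implements: the
coordinate conventions and mapping schemes, the correlation-atlas and
vector-map machinery, the statistical comparisons, the synthetic cohort
model, and the design decisions taken where the methodology left genuine
choices open.

## The mapping problem

Glaucomatous loss of retinal ganglion cells thins the macular ganglion cell
layer (GCL) and inner plexiform layer (IPL) on OCT and depresses visual
field (VF) sensitivity on perimetry. Relating the two spatially is harder
than it looks: OCT averages thickness over sectors much larger than the
0.43° perimetric stimulus; ganglion cells in the central ~8° are displaced
radially from the photoreceptors they serve; and both modalities carry
substantial test–retest variability. Two mapping schemes formalize the
comparison:

* **Conventional (CMA).** An 8 × 8 grid of 3° × 3° superpixels spans the
  central 24°, fovea-centred, oriented along the fovea–Bruch's-membrane-
  opening (FoBMO) axis and then rotated so the analysis grid is horizontal.
  The 68 locations of the 10–2 pattern, flipped across the horizontal
  midline into retinal orientation, group into 40 VF units of 1–4 locations;
  sensitivity is averaged within units.
* **Localized (LMA).** A 12 × 12 grid of 2° × 2° superpixels whose centres
  coincide with the stimulus locations; every location is its own unit. This
  is the natural scheme for fundus-tracking perimetry, which projects each
  stimulus at a fixed retinal position.

All analysis is carried out in right-eye visual-field degrees (positive *x*
temporal field, positive *y* superior field); left eyes are mirrored in *x*,
and the retinal correspondence is the vertical flip only.

### The 10–2 pattern and unit assignment

The 10–2 pattern is generated as all odd-integer pairs with
*x*² + *y*² ≤ 82, which yields exactly 68 locations, 17 per quadrant, 2°
apart — the published layout. A device-exact coordinate table can be
substituted via `read_vf_pattern()`; every downstream step consumes the
pattern object, not the generation rule.

Because stimulus coordinates are odd integers, some fall exactly on the 3°
cell boundaries of the conventional grid (at ±3° and ±9°). Cell intervals
are therefore half-open with the closed edge on the **peripheral** side: a
boundary location joins the cell farther from fixation. This is the only
simple axis-aligned rule we found that reproduces the published unit
structure — 40 non-empty cells with 1–4 members — and it is applied
symmetrically in *x* and *y*. The resulting unit sizes are 1, 2 and 4;
no 3-member units arise from the symmetric layout.

The exact C1–C40 memberships of the original description are not published
location-by-location; the reconstruction here matches every published count
(68 locations, 40 units, sizes within 1–4, 64 and 144 superpixels) but
individual memberships are a reconstruction, not a transcription.

### Grid rotation and exclusions

`rotate_grid()` stores a rotation about the fovea; membership queries
counter-rotate coordinates, so centre-to-centre distances are exactly
rotation-invariant. In simulation each eye receives its own FoBMO angle,
drawn Normal(−7°, 2.5°) — a typical anatomical distribution; the published
protocol applies per-eye rotation without reporting angles. Superpixels
overlying the optic nerve head can be excluded (`apply_onh_exclusion()`);
with the default disc model (centre 15.5° nasal, 1.5° inferior, radius 2°)
the disc lies outside the 24° grid and nothing is excluded. Which cells were
excluded in the original analysis is unstated, so the exclusion is
configurable and defaults to empty; excluded cells are masked from atlases
and can never become vector targets.

## Atlases, vectors, comparisons

Sensitivity in dB is converted to the linear scale 10^(dB/10) (from
*dB* = 10·log₁₀(1/L)) **before** averaging within units. Whether the
original analysis averaged before or after linearization is not stated;
linear-first is the default because the linear scale is the one on which
sensitivities are subsequently correlated, and `average_scale = "db"`
provides the alternative.

For each unit the Pearson correlation with thickness is computed in *every*
superpixel of the grid across all subjects, patients and controls pooled.
Pairs with zero variance on either side are **undefined** and stored as
`NA`, never as 0 — treating them as 0 would systematically bias the argmax
toward damage-free superpixels. A cohort with no between-subject variance
anywhere (e.g. noise-free healthy controls) raises an error instead of
returning a degenerate atlas.

The vector map takes, per unit, the argmax over defined, unmasked entries.
Correlations within `tie_tol = 1e-9` of the maximum are tied; ties break
first toward the smallest centre distance to the mapped superpixel
(conservative toward a "hit"), then toward the lowest superpixel id. The
tolerance matters: in noise-free simulations with a single shared damage
shape, every damaged superpixel's thickness is an affine function of the
damage depth, so their correlations with any monotone function of depth are
*exactly* equal in population and differ only by floating-point rounding;
the tolerance recognises this tie and the distance rule then resolves it to
the mapped superpixel. Vector length is the Euclidean distance between
superpixel centres in degrees (on the 3° grid the largest possible length is
9√2 ≈ 12.7°, consistent with the published extrema). A unit whose entire
atlas row is undefined yields an `NA` vector row rather than an error, since
legitimate noise-free experiments produce such units; summaries report them
as undefined.

Scheme and modality comparisons use the two-sided Wilcoxon signed-rank test
after Fisher z-transformation, exact for ≤ 25 informative tie-free pairs and
the continuity-corrected normal approximation otherwise; zero differences
are dropped and identical vectors report *p* = 1. How the original analysis
paired 40 conventional against 68 localized values is not described, so
`pair_units()` offers two rules and reports which was used: the default
averages the Fisher-z of each conventional unit's member locations (40
pairs); the alternative pairs each unit with its spatially nearest localized
location. Hemimacula splits group per-unit maxima by the hemifield of the
mapped superpixel centre. No multiplicity correction is applied, matching
the original single-comparison design; α = 0.05 two-sided.

## The synthetic cohort model

The simulator exists because the clinical dataset is not deposited; it
reproduces the *statistical structure* the analysis assumes, with known
ground truth, so that the machinery can be validated.

**Normative profile.** GCL and IPL thickness is rotationally symmetric:
a gamma-shaped rise from the foveal pit to a peak where ganglion cell somas
stack in multiple layers, then a Gaussian decay to a peripheral floor where
somas form a single layer. Defaults (µm, degrees): GCL fovea 8, peak 55 at
4.5°, floor 20, decay scale 4; IPL fovea 12, peak 44 at 4°, floor 21, decay
4.5. These give a healthy posterior-pole grid mean of ≈ 32 µm GCL, placing
healthy eyes in the mildest severity tertile with margin, and satisfy the
anatomical constraint of rapid thinning beyond ~8°.

**Damage.** Arcuate patterns are products of compact-support smoothstep
windows in polar angle and eccentricity, scaled by a depth in [0, 1], and
hard-clamped to one hemiretina — nerve fibre bundles do not cross the
horizontal raphe. Overlapping patterns combine as complementary products so
the fraction stays in [0, 1]. Severity classes draw depth, angular extent
and eccentricity band from ranges chosen so that the resulting mean GCL and
mean deviation land in the intended tertile (severe: depth 0.75–0.95, extent
130–180°; middle: 0.5–0.8, 90–140°; mild: 0.25–0.55, 50–100°); a candidate
subject is kept only when both metrics agree on the targeted tertile,
otherwise redrawn. The tertile bounds are the published ones: mean GCL
≤ 23 / 24–27 / ≥ 28 µm (rounded to the nearest µm, since the bands are
printed as integers) and MD ≤ −10 / (−10, −4) / ≥ −4 dB, half-open at −10.

**Structure–function link.** Sensitivity at a retinal point is
`healthy(ecc) − max_loss · damage + noise`, clamped to [0, 35] dB, with the
healthy surface 33 dB − 0.1 dB/°. A linear-in-damage dB link with a floor is
the simplest monotone link consistent with the thinning–sensitivity
reasoning the schemes rest on; `max_loss` (default 35 dB) makes full damage
reach the perimetric floor. Damage is read at the ganglion cell position of
the projected stimulus: displacement is radial, `dmax · exp(−ecc/τ)` with
dmax = 2°, τ = 3°, zero at or beyond 8° — the published model range of 1–3°
centrally, vanishing where photoreceptors and ganglion cells align.

**Noise.** Four sources, each configurable and each off in ground-truth
recovery experiments: (i) per-superpixel thickness noise, Gaussian,
truncated at 0, with SD referenced to the 3° cell (default 2 µm) and scaled
inversely with cell side — a smaller cell averages fewer A-scans, so its
mean is noisier, which is the signal-to-noise mechanism behind the
averaging analyses; (ii) sensitivity test–retest noise whose SD grows
exponentially as sensitivity falls (the classic frequency-of-seeing
behaviour), parameterized by its value at the healthy baseline (default
1.5 dB) and capped at 6 dB; (iii) fixation jitter for standard perimetry,
isotropic Gaussian per presentation (default 1.5°), zero for tracked
perimetry; (iv) between-subject heterogeneity — a multiplicative thickness
scale (SD 0.06) and an additive sensitivity offset (SD 0.8 dB).

**Mean deviation** is the unweighted mean of (measured − healthy) dB over
the 68 locations. Device MD weights locations by normal variance; the
weights are proprietary and the reference surface here is exactly known, so
the unweighted mean is used and documented as an approximation.

**Quadrature.** Cell averages (thickness and ground-truth damage exposure)
use a fixed 5 × 5 interior lattice per cell — deterministic quadrature, so
noise-free runs are exactly reproducible and the same operator serves both
the generator and the ground-truth bookkeeping.

What the simulator does **not** emulate: B-scan/image-level structure and
segmentation error correlated along scan lines, perimetric learning and
fatigue effects, reliability indices, floor effects of the OCT
segmentation, axial-length scaling of degrees to millimetres, and
anatomically realistic (Drasdo-type) displacement fields beyond the radial
exponential. Tests passing on synthetic cohorts therefore validate the
analysis machinery and its contracts, not clinical effect sizes.

## Numerical and testing choices

* Correlations are computed by `stats::cor` and validated in the test suite
  against the definitional sum formula at absolute tolerance 1e−9 on small
  cohorts; the signed-rank p-value is validated against exhaustive
  enumeration over all 2ⁿ sign assignments for n ≤ 10.
* Null calibration of the paired comparison draws both arms of every pair as
  sample correlations from the same bivariate normal law (ρ = 0.6, 15
  observations, 40 pairs, 200 replicates) — identical generative link and
  noise, independent pairs — and checks the rejection rate at α = 0.05.
* Ground-truth recovery uses cohorts sharing one damage template with depth
  ramped across subjects, all noise and displacement off and a common FoBMO
  angle, so the affine-tie argument above applies exactly; focal-damage
  experiments add 1 µm thickness noise, under which the argmax orders
  superpixels by damage overlap.
* Mechanism checks (aggregation and tracking) run three full 48-subject
  cohorts and compare paired per-unit Fisher-z differences — the paired
  statistic is far more stable than a difference of medians. The test suite
  sizes all other cohorts at 8–16 subjects, which keeps the full suite under
  a minute while leaving every contract exercised.
* `simulate_cohort()` and `build_cohort()` seed a local RNG stream and
  restore the caller's state; identical seeds give byte-identical cohort
  exports. The pipeline writes every figure's data as a CSV twin so no
  number exists only in a figure.

## Known limitations

* The reconstructed C1–C40 memberships cannot be verified location-by-
  location against the original figure, only against its printed counts.
* The tertile consensus rule (both metrics must agree) is stricter than the
  original recruitment description, which enrolled consecutively within
  tertiles; it makes severity classes cleaner at the cost of rejecting
  borderline draws.
* The linear-in-damage link saturates at the 0 dB floor but has no
  perimetric ceiling effects; correlation magnitudes from the simulator are
  therefore best treated as qualitative.
* One eye per subject and a single exam per modality are simulated;
  test–retest designs would need repeated `simulate_exam()` calls.
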