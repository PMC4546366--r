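---
title: "Regional fractional area change: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional fractional area change: models, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records the scientific model behind `rfackit`, the conventions
the implementation fixes where several readings were defensible, and what
the synthetic phantom does and does not establish about real data.

## 1. The measurement model

Input is a cine study: one binary cavity segmentation per short-axis slice
and cardiac phase, slices ordered apex → base, with pixel size and slice
spacing in mm. Segmentation itself is out of scope — masks are taken as
given, and the phantom emits them directly.

**Phase selection.** End-diastole (ED) and end-systole (ES) are the phases
of maximal and minimal total cavity area summed over slices — one global
pair per study, not per slice or sector. A per-sector phase choice would
bound RFAC away from negative values and hide dyskinesis (paradoxical
systolic bulging), which the index is meant to expose. Ties go to the
earlier phase; a study with constant total area is flagged degenerate.

**Sector decomposition.** Each slice's cavity is split into six 60° wedges
about the cavity centroid of that slice's ED frame. The centroid is held
fixed across phases, so wedges are stationary and RFAC measures motion
relative to a fixed frame; a per-phase centroid is available
(`sector_areas(..., centroid = "per_phase")`) for studies with substantial
bulk translation. Angles are measured from image "up" (−y), increasing
clockwise in image coordinates; the anterior sector starts at
`reference_angle_deg`. No anatomical landmark rule is hard-coded: the
orientation of the sector wheel relative to anatomy is acquisition-specific
and is supplied as configuration.

Every cavity pixel is assigned by the polar angle of its center to exactly
one wedge, with half-open angular intervals `[start, start + 60°)` breaking
boundary ties deterministically. This makes sector areas conserve the total
cavity area *exactly*, which the tests assert to machine precision.

**RFAC.** Per (slice, sector) cell,
`RFAC = 100 · (EDA − ESA) / EDA`, in percent. Cells with zero
end-diastolic area are marked missing (not zero) and logged; RFAC may be
negative, and can never exceed 100.

**Slice resampling.** Ventricles are covered by different slice counts
(typically 6–8), so per-sector RFAC profiles are interpolated to 10 slices
before averaging across subjects. Slice positions are normalized to [0, 1]
by index, with equal spacing regardless of physical gaps — resampling is by
slice position in the stack, not by physical coordinate, so subjects with
different ventricle lengths land on a common grid. The interpolant is an
interpolating cubic spline; the end condition is not-a-knot by default
(exact on polynomials up to degree 3, hence exact on any linear profile),
with a natural spline available by option. `stats::spline` offers no
not-a-knot end condition, so both splines are implemented directly as a
small linear system in the knot second derivatives; the test suite checks
the natural variant against a dense `stats::spline(method = "natural")`
evaluation to 1e-9 and the default against exact cubics. Sectors with fewer
than four usable slices fall back to linear interpolation with a warning;
missing cells are dropped from the fit.

**Mid-apical remote-wall indices.** iRFAC and pRFAC are the means of the
inferior and posterior sectors over resampled slices 2–7 (1-based): the
apex slice is excluded because apex motion causes partial-volume artifacts,
and the three basal slices because the base is not involved in an anterior
infarct. ipRFAC is the per-subject mean of the two. These are the "remote,
non-infarcted wall" indices: in an anterior infarction model they quantify
secondary loss of contraction away from the infarct territory.

**Global function.** Stacked-disk volumetrics: EDV (ESV) is the summed
total cavity area at ED (ES) times the slice spacing (1 mm default; the
acquisition's slice thickness may overlap, but spacing governs volume);
SV = EDV − ESV; EF = 100·SV/EDV. With uniform spacing EF is algebraically
the EDA-weighted mean of the per-cell RFAC on the original grid; the
package verifies this identity to 1e-9 on every phantom. It is the formal
statement of why a regional index can resolve effects EF averages away.

**Bull's-eye.** Group-mean maps are drawn with the apex ring at the center,
consecutive slices outward to the base, wedges placed by the same angle
convention as the geometry (so figure and measurement agree), a red → green
color ramp over a *fixed* configurable range (default 0–100%) so maps of
different groups share a scale, hatching for missing cells, and per-cell
marks `•` (0.05 < p < 0.1), `*` (p < 0.05), `**` (p < 0.01).

## 2. The phantom and the synthetic cohort

The phantom is a geometric cavity model, not an MR simulation: no k-space,
coils, gating, myocardium or papillary muscles. On slice `s` the cavity
boundary is `ρ(θ, t) = R(s)·(1 − c(θ, s)·g(t))` with `R` the end-diastolic
radius (a prolate-hemisphere profile apex → base by default, scaled so a
7-slice, 1 mm stack encloses ≈ 39 µl), `c` the per-sector radial
contraction amplitude, and `g` a raised-cosine waveform with `g = 0` at ED
and 1 at ES. Contraction acts on the radius, so area changes quadratically
and a sector with uniform `c` has closed-form
`RFAC = (1 − (1−c)²)·100` — the identity every recovery test is written
against. Adjacent sectors with different amplitudes are blended by a cosine
taper over a 10° transition arc (non-physical steps in the boundary would
otherwise leak area between wedges); the analytic ground truth integrates
the *blended* field, so it remains exact even across boundaries. Boundary
noise is modeled as per-pixel radial jitter (SD in pixels). Same seed,
bit-identical masks.

At 256² resolution a jitterless phantom's measured RFAC is within 1%
absolute of the closed form in every sector (about 0.7% in practice); at
the default 128² the discretization error is a little larger, which is why
the accuracy tests run at 256².

The cohort generator emulates a three-group longitudinal infarction study:
12 subjects per group (sham, untreated infarct "MI", treated "MI+Val"),
followed at baseline, 24 h, 1 and 4 weeks. Group mean contraction fields
are back-solved from target regional RFAC levels via
`c = 1 − sqrt(1 − RFAC/100)`: the anterior / antero-septal / lateral
territory from apex to mid-ventricle (slice positions ≤ 0.7) collapses to
RFAC ≈ 3–6%, the remote inferior / posterior / septal wall falls to ≈ 20%
(untreated) or ≈ 32–35% (treated) over the follow-up, and the base is
spared. Remote-wall targets and end-diastolic volumes (dilation is modeled
by scaling the radius profile, up to ≈ 117 µl in the untreated group at 4
weeks) follow the group-mean levels typical of an anterior
coronary-ligation mouse model. Between-subject variation is a shared
contraction offset (SD 0.05, giving ipRFAC SDs near 8–10 points) plus a 5%
CV on EDV. Mortality is modeled as constant per-day hazards confined to
the first week after randomization (sham 0, MI 0.03, MI+Val 0.012 per
day), matching a design where late deaths are not expected; follow-up is
administratively censored at 28 days. Atrial traces are ellipses whose
solid of revolution about the supero-inferior axis hits target Vmin/Vmax
(axis ratio 1.3), with appendage midlines of target arc length and duct
diameters set by target fractional shortening — enough structure to
exercise the echo pipeline end to end, with 10% between-subject CV.

What passing phantom tests shows: the geometry, phase detection,
interpolation, summarization and statistics are implemented correctly, and
parameter recovery is exact up to discretization. What it does not show:
robustness to segmentation error, through-plane motion, papillary muscles
in the cavity, arrhythmic gating artifacts, or mis-oriented sector wheels —
all properties of real data the phantom deliberately does not model.

## 3. The statistical battery

* **Pre-treatment check** (24 h): one-way ANOVA with two orthogonal
  Helmert-type contrasts — (a) sham vs the average of the two infarcted
  groups (did surgery work?) and (b) MI vs MI+Val (was randomization
  unbiased?). Implemented as explicit contrast columns in `lm`; per-contrast
  t and p are returned, with the omnibus F as an attribute. Zero
  within-group variance everywhere yields undefined p-values and a
  degeneracy flag rather than a silent 0/0.
* **Post-treatment comparisons**: treatment-contrast ANOVA against the MI
  reference.
* **Time constancy in shams**: one-way repeated-measures ANOVA with subject
  as the error stratum, followed by paired t-tests with Holm's step-down
  adjustment; incomplete subject × timepoint grids are an error (no
  imputation).
* **Regional maps**: cell-by-cell unpaired t-tests on the resampled
  10-slice grid. The default is the pooled-variance two-sample t (the plain
  "unpaired t-test"); Welch is a flag. Raw p-values by default — the
  bull's-eye marks raw significance across 60 cells, and a
  Benjamini–Hochberg option exists for users who want the correction.
* **Power**: two-sample t power via the noncentral t with pooled SD
  `sqrt((sd1² + sd2²)/2)`, noncentrality `δ / (SD·sqrt(2/n))`, `2n − 2` df,
  one- or two-sided. Sidedness is exposed because conventions differ across
  power software; the routine is validated against a Monte-Carlo oracle
  (200 000 simulated trials in the tests), which is treated as the
  authority for this computation. At n = 12/group, δ = 14, SDs 10.4 and
  17.3, α = 0.05 it reports 63.2% two-sided (75.3% one-sided).
* **Mortality**: Kaplan–Meier product-limit curves and the log-rank test
  via the `survival` package; the no-events case is flagged rather than
  erroring.

Type-I error of the t maps, the Helmert contrasts and the log-rank is
checked on 1000 null simulations each (binomial tolerance around α = 0.05),
and Holm output is checked against the hand-applied step-down definition.

## 4. Expression screens

Intensities are modeled and filtered on the log scale; fold changes are
ratios of linear-scale group means.

**Filtering** (defaults: floor 125 at the 33rd percentile, variance test at
α = 0.05): (a) drop probes whose 33rd intensity percentile is below the
floor — low-expressed probes near the detection limit; (b) keep a probe only
if its log-intensity variance significantly exceeds the median probe
variance, by the chi-squared statistic `(n−1)s²/median(s²)` on `n−1` df —
an informativeness filter; (c) collapse multiple probes per gene symbol to
the largest-IQR probe, ties broken by probe ID. Rule (b)'s reference (the
median variance) is part of the filter's calibration: it is stored in the
returned object's audit log and reused on re-application, so filtering is
idempotent. Probes without gene symbols are kept under their probe ID
unless dropped by option.

**FDP control with confidence.** Genes are ranked by per-gene p-values
(one-way F across classes, or the Pearson correlation test against a
quantitative trait such as ipRFAC). Class labels (or trait values) are
permuted across arrays — 1000 permutations by default, with exhaustive
enumeration of the label arrangements whenever their number does not exceed
the requested count, making small instances deterministic and
seed-independent. For a candidate list of the top `k` genes, the number of
false discoveries is estimated per permutation as the count of permuted
p-values at or below the observed k-th smallest; the list grows while at
least `conf` (80%) of permutations keep the false-discovery proportion at
or below `fdr` (10%) — a step-down rule, so the returned list is the
largest prefix of acceptable sizes, and raising `fdr` or lowering `conf`
can only enlarge it. The observed labeling is always a member of the
sampled permutation set, and reported per-gene permutation p-values use the
add-one convention `(b + 1)/(B + 1)`. Under a simulated global null the
procedure returns a non-empty list in ≤ 20% of replicates (checked over 200
replicates with binomial tolerance), which is the defining property of the
80%-confidence bound; the internal order statistics of any particular
legacy implementation are not reproduced, only this property.

**Pairwise screens**: per comparison (untreated vs sham, untreated vs
treated), a pooled-variance t-test on log2 intensities at α = 0.01 plus a
signed linear fold-change gate at ±1.2 (ratio if ≥ 1, negative reciprocal
otherwise); a gene survives if both gates pass in at least one comparison,
and its direction label (up/down under treatment) is the sign of the
treated-vs-untreated mean difference.

## 5. Numerical conventions and degenerate inputs

* Pixels are 0-based centers; polygon contours rasterize by even-odd
  scanline with half-open fills, so an axis-aligned w×h-pixel square covers
  exactly w·h pixels and abutting contours tile without double counting.
* Sector wedges use half-open angular intervals; conservation of total
  area is exact by construction.
* A cavity radius that vanishes anywhere (contraction ≥ 1) is rejected at
  specification time with the offending sector and slice named.
* Empty masks, inconsistent dimensions, mismatched TIFF page counts,
  zero-length atrial axes, self-intersecting atrial polygons (checked by
  pairwise segment intersection), vmin > vmax, and fold-change gates < 1
  are all hard errors; zero-EDA cells, sparse-slice splines and
  all-missing sectors degrade softly with warnings.
* Simpson's-rule volumes use the single-plane method of disks: 20 disks by
  default (configurable), chords taken as full disk diameters, stations at
  strip midpoints over the polygon's extent along the axis direction. A
  rectangle (cylinder of revolution) is exact at any disk count; a circle
  (sphere) converges within 0.5% by 200 disks.

## 6. Problem sizes in the shipped tests

The suite exercises: phantoms at 48²–128² for behavioral tests and one
256² phantom for the accuracy contract; 1000-replicate null batteries for
the classical tests; 200-replicate null batteries at 60–80 genes, 12–18
samples and 400–500 permutations for the FDP-control property; and a
reduced synthetic cohort (2–3 per group, 48²–64² matrices) for end-to-end
pipeline checks. The acceptance script runs the full 12-per-group cohort at
96² over two timepoints. These sizes are the package's validation choices:
large enough for each property's tolerance, small enough that the whole
suite runs in about a minute.

## 7. Known limitations

* The sector wheel's anatomical anchoring is configuration, not inference;
  cross-study comparability requires a consistent `reference_angle_deg`.
* Volumes assume stacked disks with nominal spacing; no partial-volume or
  slice-profile correction.
* The echo module measures mono-plane traces with circular-disk symmetry;
  real atria are not solids of revolution, so volumes are convention-bound
  (as they are on the scanner software side).
* Group means of ratio indices (e.g. LA EF) are means of per-subject
  ratios, which will not equal ratios of group-mean volumes.
* The expression normalization is pluggable and defaults to analyzing the
  matrix as given (log2 internally); reproducing counts from any specific
  array pre-processing stack (variance stabilization, robust spline
  normalization) requires running that stack upstream.
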