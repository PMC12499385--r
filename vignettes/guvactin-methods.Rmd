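---
title: "Quantifying actin-induced GUV remodeling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying actin-induced GUV remodeling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guvactin)
```

## Scope

`guvactin` quantifies how branched, Arp2/3-nucleated actin networks
remodel giant unilamellar vesicles (GUVs) in two-channel
(lipid / actin) single-plane fluorescence time lapses, and models why
an actin network growing on liquid-disordered (Ld) membrane domains
arrests their coalescence. Because such experiments are rarely
published with raw images, the package ships a synthetic-image
generator with embedded ground truth; every measurement stage is
validated by round-trips against it.

The pipeline has five computational stages:

1. **Synthetic imaging** — equatorial cross-sections of GUVs with a
   Gaussian membrane ring, optional brighter Ld arcs, and an actin
   shell / asymmetric shell / comet, with Poisson + Gaussian noise.
2. **Morphometry** — contour segmentation; equivalent-area diameter;
   Feret-based ellipticity; actin shell thickness and
   symmetry-breaking angle; structure classification; growth-rate
   fitting.
3. **Radial profiling** — per-degree peak intensities along the
   perimeter, normalization, Ld-domain calling at the 0.2 level,
   actin-on-domain scoring.
4. **Domain dynamics** — coalescence time courses, the domain number
   ratio `N_t / N_0`, initial-count categories, and the group tests
   (Mann–Whitney U, Wilcoxon signed-rank, Welch's t).
5. **Coalescence physics** — Saffman–Delbrück mobility, contact-time
   and corona-overhang estimates, and a stochastic
   diffusion–coalescence simulator on the sphere.

## The synthetic scene and what it does (not) emulate

A scene is described by `synth_spec()`. The membrane is a Gaussian
ridge of width `membrane_ring_sigma_um` (default 0.3 µm, the
diffraction-limited scale of epifluorescence at high NA) at radius
d/2; this gives sub-pixel peak localization a realistic test. The
default sampling is 0.2 µm/px, a typical 63×-objective scale; the
default diameter range mirrors the 10–60 µm band that microfluidic
traps select. Actin structures:

* *symmetric shell* — an annulus of uniform thickness;
* *asymmetric shell* — thickness modulated by a smooth unimodal
  angular profile `t(θ) = t_max · (f + (1−f) cos⁴((θ−θ₀)/2))`
  peaking at the break angle θ₀, with floor fraction
  `f = asym_min_frac = 0.2`;
* *comet* — a tapered tail polygon (half-width 25° → 5°) of length
  2.5 GUV radii; experiments show comets but do not parameterize
  them, so the taper is a modeling choice.

Phase-separated GUVs carry `n_domains` Ld arcs on which the lipid
intensity is multiplied by `ld_lipid_gain` (default 8). The gain
default matters: the fluorescent lipid partitions strongly into the
Ld phase, so the Lo ring is several-fold dimmer; quantitatively, any
gain below 5 would leave the normalized Lo signal above the 0.2
domain-calling threshold and make the calling rule degenerate. Actin
is confined to the Ld arcs when `actin_on_ld_only = TRUE` (the
default whenever domains are present), emulating nucleation on Ld.

Noise is Poisson on the signal plus an additive Gaussian background —
the usual shot-noise + read-noise model; the experimental camera
calibration is unknown, so intensities are arbitrary float units.
Not emulated: the 3D point-spread function, z-stacks, photobleaching,
membrane nanotubes, and out-of-focus light. Passing round-trip tests
therefore demonstrates correctness of the measurement definitions,
not robustness to every artifact of real epifluorescence.

## Morphometry definitions

* **Diameter**: `d_GUV = 2 sqrt(Area/π)` from the contour area.
* **Ellipticity**: `100 · L_MaxPerp / MaxFeret`, where the maximum
  Feret diameter is the largest pairwise distance between contour
  points and `L_MaxPerp` is the largest chord perpendicular to that
  direction. For a convex polygon the chord length versus offset is
  concave and piecewise linear, so the maximum is attained at a
  vertex offset — `ellipticity()` evaluates exactly there, and the
  test suite checks it against a dense brute-force scan. Ties in the
  Feret direction are broken towards the smallest angle to +x.
* **Actin thickness**: the longest radial distance between the
  membrane contour and the outer edge of the actin network over 360
  rays; its angle is the symmetry-breaking orientation (0° = +x,
  counter-clockwise — the convention used consistently everywhere).
  The outer edge on a ray is the outermost sample exceeding
  `background + k·σ` (k = 3 by default). Interactive analyses judge
  this edge by eye; a fixed k makes it reproducible.
* **Structure class**: symmetric shell if the relative thickness
  modulation `(max−min)/max < a_sym` (default 0.3); comet if actin
  reaches beyond `r_comet` (default 1.5) GUV radii within a sector
  narrower than 90°; otherwise asymmetric shell. Experimental
  classifications are assigned by eye; these two thresholds make the
  class tallies reproducible and are echoed in every output.
* **Growth rate**: OLS slope of thickness versus time (gels thicken
  quasilinearly at 0.1–0.3 µm/min in this regime).

### Segmentation

The interactive wand-tool delineation is replaced by: threshold at
*background median + 3 MAD* (with a small relative floor so noise-free
images threshold just above background), hole-filling of the ring,
connected-component labelling, selection of the largest component (or
the one enclosing a seed point), then sub-pixel refinement that
relocates each of 360 contour radii to the parabolic-interpolated peak
of the radial intensity profile. Two numerical points are worth
recording. First, a histogram-split threshold (e.g. Otsu) fails on
phase-separated rings: with an 8-fold Ld/Lo contrast the split lands
*between* the two ring populations and the mask fragments into arcs.
A background-anchored threshold keeps the ring connected regardless of
the contrast. Second, the raw mask contour sits on the outer tail of
the Gaussian ridge and overestimates the enclosed area by ~5–10%;
refining to the ridge peak reduces the area error to well under 1%.

Thickness measurement has a related subtlety: the actin edge threshold
is anchored on the *frame border strip* rather than on an annulus just
outside the contour, because a thick shell (or a comet) can reach into
that annulus and inflate the spread estimate. The rendering margin
(and, in practice, any sensible field of view) guarantees the border
is structure-free. Radial traces are lightly smoothed (3-sample moving
average) before thresholding so that a single noise sample cannot
masquerade as the network edge.

## Radial profiling

Per degree, intensities are sampled by bilinear interpolation every
0.5 px out to 1.5 GUV radii. The reported per-angle value is the mean
over the contiguous half-maximum run around the global maximum of the
background-subtracted trace — a parameter-free replacement for the
unspecified "mean on the peak" window; for a Gaussian ridge of
amplitude A it evaluates to ≈ 0.81 A, which the tests verify against
the closed-form integral. Background is the median beyond 1.2× the
maximal contour radius, which is immune to the GUV and its corona.
Each channel is then normalized by its own per-GUV maximum (1 = channel
maximum, 0 = background), making the pipeline invariant to global
intensity scaling.

Ld domains are the contiguous runs where the normalized lipid signal
*strictly* exceeds 0.2, merged across the 0°/360° wrap. Runs narrower
than the angle subtended by 1 µm at the GUV radius — the smallest
domain resolvable optically — are discarded; the filter can be
disabled (`min_width_deg = 0`) and its value is recorded in the
output. Normalization (and hence the 0.2 threshold) is applied *per
frame*; normalizing a whole time series to its first frame is a
defensible alternative, but per-frame normalization is what a
per-image analysis does and is robust to slow focus drift.

The actin-on-Ld score is the mean normalized actin over all domain
angles divided by the maximum within the domains (1 = the maximal
actin fluorescence on that GUV's domains, 0 = background; 0 when no
domains exist). On noise-free images with angularly constant actin
this score is 1 by construction for any actin density; it becomes
discriminative under photon noise, where a dim, spread-out network
has a larger max-to-mean ratio than a dense colocalized one — the
direction the experiments report.

## Domain dynamics

`build_trajectory()` takes per-frame counts, anchors `N0`, `N10`,
`N60` at the nearest frames within ±2 min (acquisition cadences vary),
and forms the domain number ratios `N10/N0`, `N60/N0`. Ratios above 1
can only arise from counting noise (the model forbids fission) and are
clipped to 1 with a warning. Initial-count categories are
`n_d = 2`, `2 < n_d ≤ 10` (inclusive upper bound), `n_d > 10`;
trajectories with `N0 < 2` are grouped with the first category so the
three classes always partition a data set.

Group tests follow the design: independent + nonparametric →
two-sided Mann–Whitney U (exact for n ≤ 8 per group without ties,
normal approximation with tie correction otherwise — the behavior of
`stats::wilcox.test`, which the test suite cross-checks against full
enumeration on 5-vs-5 samples); paired → Wilcoxon signed-rank;
independent + normal → Welch's t. Tiers: n.s. p > 0.05, * ≤ 0.05,
** ≤ 0.01, *** ≤ 0.001.

## Coalescence physics

A membrane inclusion of radius r has the Saffman–Delbrück mobility

D(r) = k_BT / (4π η_m) · ln(η_m / (η_f r)),

valid for r below the Saffman–Delbrück length η_m/η_f (10 µm at the
defaults η_m = 10⁻⁸ Pa·m·s for liquid-ordered membranes,
η_f = 10⁻³ Pa·s for water); D = 0 exactly at the length and the
function refuses radii beyond it. For a 1 µm Ld domain this gives
≈ 7.5 × 10⁻¹⁴ m²/s. A domain exploring a patch of linear size
R ≈ 5 µm reaches its neighbor on the scale τ = R²/4D ≈ 80 s, during
which a gel growing laterally at v_gel = 2.5 nm/s adds a
v_gel·τ ≈ 200 nm overhang — larger than the ≈ 100 nm mesh size ξ of a
branched network, which is the steric blocking criterion
(`overhang > ξ`, strict: a fringe exactly one mesh wide is taken as
penetrable).

`simulate_domains()` realizes this picture as Brownian motion of
n₀ circular domains (initial radius 1 µm) on the surface of a sphere
of radius `R_guv`, Euler–Maruyama steps in the local tangent plane
(per-axis s.d. `sqrt(2 D(r_i) dt)`) re-projected along great circles.
Domains merge when their geodesic center distance falls below the sum
of radii; the merged domain conserves area (r = sqrt(r_i² + r_j²)) and
sits at the area-weighted centroid. Modes: `bare` (free coalescence);
`spvca` (all D multiplied by `f_spvca = 0.3` — an assumed
diffusion-slowing factor for NPF-coated domains, exposed in the
parameters and *not* a measured value); `actin` (coronas nucleate at
t = 0 and grow at `v_gel`; once the overhang of either partner exceeds
ξ, merging is blocked). Coronas starting flush with the domain edge
give a ≈ ξ/v_gel = 40 s unblocked window, reproducing the observed
slight early coalescence followed by a plateau.

Numerical choices: default dt = 0.05 s (an error is raised when the
RMS step exceeds the smallest domain radius; the long property runs in
the tests use dt = 0.25 s, still 4× below that bound); initial
placement is uniform rejection sampling without overlap; merges are
processed closest-first within a step; all randomness flows from one
integer seed, and repeated runs with the same seed are bit-identical.

Two modeling decisions deserve emphasis:

* **The two-domain state is absorbing.** Observed bare GUVs coarsen to
  a stable count of two, which we read as complete coarsening — one
  patch per phase; line tension and geometry make further "merging"
  of the two remaining macroscopic caps a different physical process.
  The simulator therefore stops merging at N = 2 in every mode.
* **Counts are reported twice.** `n_total` counts domains on the whole
  sphere; `n_equatorial` counts those intersecting the equatorial
  circle, which is what single-plane imaging sees and what
  `lapse_from_simulation()` projects into rendered arcs (overlapping
  projections are merged and logged). Trajectory statistics built
  from images are therefore equatorial by construction.

The analytic τ = R²/4D is a single-tracer, point-contact estimate. In
the simulation both partners diffuse — the relative coordinate
diffuses at 2D — and contact occurs at finite distance r_i + r_j, so
tagged-domain first-contact times concentrate around R²/8D, half the
single-tracer value and within the order-of-magnitude intent of the
estimate. The test suite asserts the simulator against the two-body
scale R²/(8D) within a factor of two (34 domains on a 30 µm GUV, where
the mean area per domain corresponds to R ≈ 5 µm).

Omitted physics: Ostwald ripening (slow compared to coalescence in
this regime and neglected deliberately), hydrodynamic domain–domain
coupling, membrane tension, domain shape relaxation, and the
logarithmic corrections of true 2D first-passage theory.

## Problem sizes and reproducibility

The shipped tests run the full measurement chain on renders of
101–449 px, growth-rate round-trips on 13-frame lapses, the domain
sweep over n_d = 2…36, 50 matched-seed simulator replicates for the
mode ordering at t = 600 s and 18 replicates of 3600 s for the
stabilization property — sizes chosen so the whole suite documents the
behavior in a few minutes while exercising every code path. All
pipeline outputs echo the thresholds and the seed that produced them,
and rerunning any stage with the same configuration reproduces the
same files byte for byte (TIFF frames are stored as 32-bit floats, so
re-read intensities agree to float precision, ~10⁻⁷ relative).

## Known limitations

* The generator's Gaussian-ridge membrane is a 2D idealization; no
  PSF convolution, so resolution-limited effects enter only through
  the ridge width and the 1 µm domain-width floor.
* Segmentation assumes one dominant ring per frame (plus an optional
  seed point for crowded fields); overlapping GUVs are out of scope.
* The contour-radius interpolation used for membrane radius per ray
  assumes a star-shaped contour — adequate for trapped GUVs, wrong
  for strongly budded shapes.
* `f_spvca` and the comet taper are modeling assumptions, not
  measurements; both are exposed as parameters.
* Equatorial counts fluctuate as domains diffuse through the focal
  band; ratio clipping at 1 absorbs upward fluctuations but the
  counts themselves remain noisy, as in the experiment.
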