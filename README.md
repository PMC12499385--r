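# guvactin

Quantification of actin-induced remodeling of giant unilamellar
vesicles (GUVs) from two-channel fluorescence microscopy, with a
physical model of why actin arrests lipid-domain coalescence.

## The problem

Branched, Arp2/3-nucleated actin networks polymerized on the outside
of GUVs reshape them in stereotyped stages — uniform shells, then
symmetry-broken asymmetric shells, then propulsive comets — and, on
phase-separated membranes, they grow specifically on the
liquid-disordered (Ld) domains and freeze the usual coarsening of
those domains. Analyzing such experiments means extracting a small
set of per-vesicle descriptors from single-plane, two-channel
(lipid / actin) time lapses:

* GUV diameter `d_GUV = 2·sqrt(Area/π)` and ellipticity
  `100·L_MaxPerp / MaxFeret` (maximum Feret diameter = largest caliper
  distance of the contour; `L_MaxPerp` = largest chord perpendicular
  to it);
* actin shell thickness (longest membrane-to-network-edge radial
  distance), its angle (symmetry-breaking orientation), the
  shell/comet class, and the thickness growth rate;
* per-degree normalized radial fluorescence profiles, Ld domains
  called where the normalized lipid signal exceeds 0.2, the domain
  count `n_d`, and the mean normalized actin fluorescence on the
  domains;
* domain-count trajectories and the domain number ratio `N_t/N_0`,
  compared across conditions with Mann–Whitney U / Wilcoxon /
  Welch's t tests.

The mechanistic model: an Ld domain of radius r diffuses with the
Saffman–Delbrück mobility `D = k_BT/(4π η_m) · ln(η_m/(η_f r))`
(≈ 7.5×10⁻¹⁴ m²/s for r = 1 µm in a liquid-ordered membrane), meets
its nearest neighbor after `τ ≈ R²/4D ≈ 80 s` for R ≈ 5 µm, while an
actin gel growing laterally at 2.5 nm/s overhangs the domain edge by
≈ 200 nm in that time — more than the ≈ 100 nm mesh size of the
network, so the corona sterically blocks coalescence. The package
implements this arithmetic and a stochastic diffusion–coalescence
simulator of domains on the sphere (bare, NPF-coated, and
actin-covered modes).

Because raw images from such experiments are generally not deposited,
`guvactin` also ships a synthetic-image generator
(`synth_spec()` / `render_guv_frame()` / `render_time_lapse()` /
`lapse_from_simulation()`) that renders two-channel GUV scenes with
known ground truth; every measurement function is validated by
round-trip against it.

## Worked example

```r
library(guvactin)

## a 30 um GUV with a 6 um asymmetric actin shell breaking at 120 deg
spec <- synth_spec(guv_diameter_um = 30, pixel_size_um = 0.2,
                   actin_structure = "asymmetric_shell",
                   actin_thickness_um = 6, break_angle_deg = 120,
                   shot_noise = TRUE, seed = 42)
frame <- render_guv_frame(spec)
morphometry_record(frame)
#>   d_guv_um max_feret_um l_max_perp_um ellipticity_pct actin_thickness_um
#> 1       30        30.27         30.11           99.48              6.354
#>   break_angle_deg  structure_class
#> 1             125 asymmetric_shell
```

The measured diameter (30 µm), ellipticity (≈ 100%: the vesicle is
round), shell thickness (6.35 µm vs the programmed 6 µm — the edge
rule reads the outer tail of the rendered network, within the ~2 px
tolerance of the definition) and breaking angle (125° vs 120° under
shot noise) recover the generating parameters, and the
thickness-modulated shell is classified `asymmetric_shell`.

```r
## does an actin corona stabilize lipid domains?  10 domains on a
## 24 um phase-separated GUV, 1 h of growth vs a bare control
tr <- simulate_domains(n0 = 10, R_guv = 12e-6, mode = "actin",
                       t_end = 3600, dt = 0.25, seed = 1,
                       sample_times = c(0, 600, 3600))
tr
#> sim_trace (actin): n0 = 10 -> 9 domains after 3600 s (1 merges)
trj <- build_trajectory(tr$n_total, tr$times_s / 60, condition = "actin")
#> N0 = 10, N10 = 9, N60 = 9, ratio_60 = 0.90

simulate_domains(n0 = 10, R_guv = 12e-6, mode = "bare",
                 t_end = 3600, dt = 0.25, seed = 1,
                 sample_times = c(0, 600, 3600))
#> sim_trace (bare): n0 = 10 -> 2 domains after 3600 s (8 merges)
```

With actin, one merge slips through the ≈ 40 s window before the
corona overhang exceeds the mesh size, then the count plateaus
(domain number ratio 0.90 after an hour); the matched bare run
coarsens all the way to the absorbing two-domain state.

Higher-level drivers are available through `run_config()` +
`run_pipeline()` (analyses: `"homogeneous"`, `"stabilization"`,
`"nd_structure"`, `"simulate"`), which write CSV/JSON results, plots
and a log — every output echoes the thresholds and seed that produced
it. `write_lapse()` / `read_lapse()` serialize image lapses as
multi-page 32-bit float TIFF plus a sidecar JSON carrying the
calibration and ground truth.

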