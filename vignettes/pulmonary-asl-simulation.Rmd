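---
title: "Simulating pulmonary ASL MRI and the intensity-threshold cost function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating pulmonary ASL MRI and the intensity-threshold cost function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulmoasl)
```

This vignette is the package's account of its science: the models, their
assumptions, the parameters that matter, and what the synthetic lung does
and does not stand in for.

## The measurement being simulated

Arterial spin labeling inverts the longitudinal magnetization of all blood
inside a band that is slightly thicker than the imaging slice, waits an
inversion time TI equal to 80% of the R-R interval, and images. Blood that
entered the slice from outside the band carries full magnetization
(`S = M_OB e^(-TE/T2) V_B`); blood that was inside the band recovers from
its initial value `m0 M_OB`
(`S = [M_OB - (M_OB - m0 M_OB) e^(-TI/T1)] e^(-TE/T2) V_B`). Only the
bright image is simulated — there is no static tissue in the model, so the
bright image stands for the bright-minus-dark difference, and over-nulled
(negative) signals are retained unclamped. At the default
T1 = 1300 ms, fully inverted blood nulls at `T1 ln 2 = 901 ms`, close to
the TI = 800 ms of a 60 bpm subject, which is why resident tagged blood
contributes little and the image is dominated by delivered blood.

Signals are stored in volume-equivalent units (the raw signal divided by
`e^(-TE/T2)`), so a voxel completely filled with fresh blood scores exactly
the voxel volume, 67.5 at the default 15 x 3 x 1.5 mm dimensions. This is
the 100% anchor of the threshold sweep: at TI = 800 ms it corresponds to an
ASL value of 75 mL/min/cm^3.

## The synthetic lung

No deposited geometry exists for the subject-specific, CT-derived lung the
study design assumes, so the generator builds a stand-in with the features
the analysis actually depends on:

* a half-ellipsoid right lung (90 x 80 x 110 mm semi-axes, ~1.66 L) with
  the hilum on the medial face, so the largest vessels concentrate
  medially and medial slices contain far more conduit blood than lateral
  ones (~47 mL vs ~0.9 mL of conduit blood in the most medial vs most
  lateral 20% at defaults);
* paired arterial and venous trees grown by volume-filling branching:
  uniform-with-bias seed points, recursive point-cloud bisection through
  the centre of mass (plane normal to the principal axis of spread, exact
  ties to the first group, degenerate splits by index halves), branches
  from the parent tip toward the sub-cloud centroid scaled by the length
  fraction (0.4, minimum 1 mm);
* each arterial terminal coupled to the nearest venous terminal through a
  short arteriole, a capillary-sheet path spanning 80% of the gap, and a
  short venule (arterioles and venules are short enough that gravity along
  them is neglected, as in the hemodynamic model);
* two anatomical asymmetries of real thoraxes, without which supine and
  prone would be exact mirror images and no posture effect could exist:
  the hilum sits dorsal of the dorsoventral midline
  (`hilum_y_frac = -0.3`), and terminal-unit density is linearly
  dorsal-weighted (`dorsal_density_bias = 0.3`, a ~1.9:1 dorsal:ventral
  density ratio), the structural bias that gravity reinforces supine and
  opposes prone.

Radii follow Murray's law `r_parent^k = sum r_child^k` from a terminal
conduit branch seed of 0.55 mm. The default exponent is k = 2.33 rather
than the classic 3: pulmonary arterial morphometry favours diameter
exponents near 2.3, and under k = 3 conduit velocity scales as `v ~ r`,
leaving mm-scale arteries at ~20 mm/s — so slow that within one TI no
capillary blood can trace back outside the inversion band and the
perfusion signal collapses. With k = 2.33 the Murray root is ~9 mm
(right-PA-like, overridden to a 15 mm trunk stub at the root), terminal
branches run at ~90 mm/s and the trunk at ~230 mm/s, and arterial transit
times are of the physiological order of a second.

Each terminal unit aggregates `n_parallel` anatomical arterioles and
venules of 0.1 mm radius (default `7.5e5 / n_terminals`, i.e. ~750 at the
desk-scale default of 1000 units — the network then represents ~7.5e5
terminal arterioles, consistent with morphometric counts at that calibre).
The number of terminal units itself is a resolution parameter, not a
physiological one; 1000 keeps the full study inside minutes of CPU.

## Hemodynamics

Conduits are 1D Poiseuille elements (`R = 8 mu L / (pi r^4)`,
mu = 3.36 mPa s, blood density 1050 kg/m^3) with gravity acting along the
centreline (`P_out = P_in - QR + rho g (h_in - h_out)`) and a linear
radius-distension law, 2% per cmH2O capped at 1.5 r0, no collapse below
zero transmural pressure. Capillary units follow a Fung–Sobin sheet:
thickness `h = h0 + alpha_c Ptm` (h0 = 3.5 um, alpha_c = 0.127 um/cmH2O)
capped at 7 um, and flow `c_sheet * f * (phi_a - phi_v)` with `phi = h^4`,
zone-2 sluicing (`phi_v = h0^4` once the venular transmural pressure is
non-positive) and a recruitment fraction `f` that rises to 1 at 10 cmH2O.
Two numerical choices depart from the bare textbook law, both to keep a
well-posed fixed point: the collapse at negative transmural pressure is a
continuous ramp down to `h0 * eps_collapse` rather than a jump (a jump
admits no fixed point when a unit sits at the discontinuity), and `phi`
continues linearly with its tangent slope beyond the thickness caps (a
saturated sheet still conducts; the literal capped law has zero
conductance once both ends saturate and the solve runs away). Within the
compliant range the law is exactly `h_a^4 - h_v^4`. Reverse-biased sheets
(venular pressure above arteriolar) close to a floor conductance —
Starling-resistor behaviour — so arterial flow stays directed root to
terminal.

The solver linearizes each element to a conductance (capillaries by the
secant of the sheet law), solves the sparse nodal conservation system with
the inlet-flow and outlet-pressure constraints (CO at the pulmonary trunk,
5 mmHg left atrial pressure), updates geometry from the new transmural
pressures under a relaxation of 0.5, and iterates to a relative pressure
change below 1e-6. The relaxation anneals after iteration 20 and capillary
conductances move at most 4x per iteration; both measures damp open/close
limit cycles on strongly heterogeneous networks. In the rigid limit
(frozen radii, capillary conductance at its reference-thickness value
`c_sheet h0^4` per cmH2O) the problem is linear and the solver agrees with
a direct dense solve to 1e-10, which the tests exercise on randomly
generated networks of up to 20 elements.

`c_sheet` is not a measured constant; it is calibrated at solve time so
that the rigid, gravity-free trunk-to-atrium drop at 5 L/min equals
10 mmHg (conduit drop measured with capillaries shorted, the remainder
assigned to the sheets). With gravity, distension and zone-2
derecruitment, the converged supine drop at 5 L/min comes out near
20 mmHg, i.e. a mean trunk pressure at the high end of normal — acceptable
for a stand-in that routes a full cardiac output through a single lung.

## ASL forward model

Every element intersecting a 15 mm sagittal slab is cut into <= 1 mm
sub-segments; each in-slab sub-segment is a parcel carrying its share of
the element's blood volume. Parcels walk upstream against the flow,
spending `length / velocity` per element; at venous junctions they split by
flow fraction (sub-parcels below 1e-6 mm^3 are merged into their siblings,
so volume is conserved exactly), and a parcel that exits the network inlet
is treated as fully magnetized outside-band blood. Velocities are the
element mean values (`Q / pi r^2` for conduits, per-channel for
arteriole/venule bundles, plug transit `Q L / V_B` for sheets).

The labeling profile is a parametric stand-in for a Bloch-simulated
inversion band: a plateau at -1 across the slice with error-function
shoulders (sigma = gap/6) centred mid-gap, reaching +1 outside. The gap
default is 7.5 mm per face, making the inversion band exceed the imaging
plane by ~15 mm in total; a measured profile can be supplied as a
`(z_mm, m0)` table. Classification as in-band uses
`|z| < half-thickness + gap`.

Voxelization accumulates signal and volume into an in-plane grid of
3 x 1.5 mm cells (one 15 mm cell through-plane) spanning the slab, with
components kept separate by vessel class. Two deposits are spread rather
than pointwise: conduit parcels over the vessel's own cross-section (a
15 mm trunk genuinely fills many voxels; without this, single voxels
receive physically impossible signal), and capillary parcels over the
in-plane disc of the terminal unit's tissue territory (radius such that
unit territories tile the lung, ~7 mm at 1000 units) — the sub-voxel
capillary bed of an acinus is space-filling, not a line. Both spreads
conserve totals exactly. The lung mask is the ellipse cross-section at the
slice centre plus any voxel that actually received blood.

## Threshold metrics and cost

Thresholding removes whole voxels whose total volume-equivalent signal
strictly exceeds `x/100 * 67.5`; equality is retained. The five cost terms
follow the study's definitions with two clarifications. `C_removed` is
implemented as the conduit fraction removed, `1 - after/prior` — the
literal wording (the ratio after/prior) defines conduit *remaining* and
contradicts the variable's name, its cost term and the stated goal of
maximizing removal; the literal reading stays available behind
`literal_c_removed = TRUE`. The delta terms are unitless fractional
absolute differences (`|COV_ASL - COV_Q| / COV_Q`, same for the gradient)
so that all five terms share scale; their references are computed from the
unfiltered capillary component. COV is the population SD over mean of
retained lung voxels; the gravitational gradient is an OLS slope of
per-bin mean value over ten height bins, regressed on per-bin mean height
(bin centres would bias the slope on irregular layouts; mean-height
regression recovers exactly linear fields to machine precision). Zero
references drop their term with a warning; ties in the argmin resolve
toward the larger threshold (least filtering).

With negative signals retained, `Q_fraction` can leave [0, 1] on slices
whose capillary component nets near zero; the bounds hold for non-negative
fields.

## Study orchestration

`ti_from_hr()` is `round(0.8 * 60000 / HR)`, reproducing all printed
protocol TIs (1000/800/667/500 and 600/558/533 ms); `sv_from_co_hr()`
rounds CO/HR to three decimals. The four scenarios vary CO through SV
(flow rate) at fixed HR, through HR (TI) at fixed SV, hold CO constant, or
vary both; `run_scenario()` solves each row at inlet flow CO = SV x HR,
images the requested slices, sweeps the threshold and reports median/mean
ASL, COV, gradient, optimal threshold and 1 mL/min/cm^3 histograms. The
posture comparison pairs per-slice COV and gradient between supine and
prone and applies a paired two-sided t-test at alpha = 0.05 (the test
choice is this package's; degenerate pairings are reported as no
difference or as a certain-direction effect rather than erroring).

## What the synthetic lung shows — and what it cannot

Passing tests demonstrate that the *pipeline* reproduces the study's
mechanism-level findings on a lung-like geometry: medial slices carry more
signal and higher COV than lateral ones; median ASL rises with stroke
volume at fixed heart rate and falls with heart rate at fixed stroke
volume; thresholding walks the image COV toward the perfusion COV before
undershooting it (an interior |dCOV| minimum); capillary flow is dorsally
biased supine; and supine heterogeneity tends to exceed prone. They do not
reproduce — and the package does not claim — the subject-specific
magnitudes of the original geometry: per-slice COV values, gradient
magnitudes, per-slice optimal thresholds (desk-scale optima land at
5-15%, well below the 30-65% of a real lung, because the synthetic
capillary field is smoother and the conduit tail thinner than reality),
or p-values. The posture direction in particular is a small effect riding
on conduit-sampling noise: across repeated generator seeds it holds in
most but not all networks.

Known limitations: a single breathing state (no FRC mechanics), no
airway tree or lobar fissures, full cardiac output through one lung,
mid-lateral slices whose capillary signal nets near zero at TI = 800 ms
(their supply path lies largely within the inversion band at this desk
scale), no coil-sensitivity or reconstruction effects, and healthy
vasculature only.

## Problem sizes and runtimes

The bundled study runs at 1000 terminal units (6998 elements), one flow
solve taking ~1 s and one slice image ~0.5 s on a single CPU; the full
acceptance recomputation (one network, eight scenario solves, five
posture networks with ten solves and fifty images) completes in about two
minutes. All randomness is seeded; identical seeds reproduce every table
byte for byte.
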