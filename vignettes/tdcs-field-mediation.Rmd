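---
title: "Field modelling, tissue geometry and mediation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Field modelling, tissue geometry and mediation: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tdcsfield` implements, as one tested chain, the computations needed to
ask whether group differences in transcranial direct current stimulation
(tDCS) field strength are mediated by body-habitus-driven tissue
geometry: head-phantom construction, finite-element field simulation,
normal-vector tissue-thickness measurement, synthetic cohort generation,
covariate-adjusted group statistics, and causal mediation analysis. This
vignette records the model, its assumptions, and the design decisions
taken where more than one defensible choice existed.

## The physical model

Under the quasi-static approximation the potential in a piecewise-
homogeneous conductor satisfies the conductivity-weighted Laplace
equation, div(sigma grad phi) = 0, and the electric field is
E = -grad(phi). The solver (`solve_potential`) uses first-order (P1)
tetrahedral elements, so phi is piecewise linear and E is constant
within each element — the standard discretization for desk-scale tDCS
modelling. Electrodes are held at fixed potentials (+1 / -1 V on the
anode and cathode contact node sets, i.e. Dirichlet conditions) and the
entire linear solution is afterwards rescaled so the injected current
equals the montage target (`scale_to_current`), 2 mA by default. This
Dirichlet-then-rescale strategy keeps the system symmetric positive
definite and sidesteps electrode-impedance modelling; the injected
current itself is evaluated from the stiffness-residual nodal currents,
which makes the discrete anode/cathode balance exact up to solver
tolerance.

Default conductivities (S/m) are scalp 0.465, compact-bone skull 0.010,
CSF 1.654, gray matter 0.275, white matter 0.126, and saline sponge 1.0
— the values in common use by tDCS simulators; all are configurable
(`conductivity_defaults`). Anisotropy, capacitive effects, and
electrode-skin impedance are out of scope.

The linear system is solved by Jacobi-preconditioned conjugate gradients
with a relative residual tolerance of 1e-10 (a few hundred iterations on
the meshes used here), with a sparse-Cholesky fallback for small
systems; at these tolerances the two agree to solver precision.

## Phantoms instead of segmented heads

All geometry lives on concentric layered-sphere phantoms
(`build_layered_sphere`). A subdivided-icosahedron surface mesh is
extruded radially with node shells placed *exactly* on every tissue
boundary, so shell interfaces are resolved by construction and a thin
layer (the 2 mm CSF) always receives at least one radial element.
Prisms between shells are split into tetrahedra with the
smallest-global-index diagonal rule, which guarantees conforming
neighbours; elements are labeled by the radial band containing their
centroid. The construction is fully deterministic: the `seed` argument
is recorded for provenance but no randomness is used.

The default layer radii (78 / 71 / 65 / 63 / 60 mm) give scalp 7 mm,
skull 6 mm, CSF 2 mm and cortex 3 mm — adult frontal-anatomy scale. A
sphere has no gyri; what it buys is analytic oracles (exact shell
volumes, radii-difference thicknesses, and a series solution for the
potential), while preserving the mechanism under study, namely that
layer thicknesses modulate the field reaching a fixed target.

Sponge electrodes are 5 x 5 cm, 5 mm thick. The square footprint is
projected on the curved scalp as a geodesic square (azimuthal-
equidistant coordinates about the electrode centre); surface triangles
whose centroids fall inside it are extruded radially and labeled
`electrode`, and the extruded outer nodes form the contact node set.
Footprint area is quantized by whole triangles, so it matches 25 cm^2
only up to the surface resolution; the suite checks a 10% tolerance at
the default test resolution. Two montage analogues are provided: a
symmetric forehead pair (anode at -35 degrees from the vertex, cathode
at +35) and an asymmetric pair (anode at -60), both anode-left, standing
in for the Fp1-Fp2 and F3-Fp2 frontal montages. ROI targets sit at
mid-gray-matter radius at +-25 degrees; MNI-space target coordinates
are treated as metadata only — phantom targets are specified directly
in mesh coordinates, since subject-space transforms are out of scope.

ROI field extraction (`roi_mean_magnitude`) averages element |E| over
elements whose centroid lies within the ROI radius (10 mm default,
20 mm variant), restricted to gray matter by default. Averages are
volume-weighted; an unweighted mean is available as a flag. Both the
tissue filter and the weighting are choices the underlying study leaves
unstated, so both behaviours are exposed and neither is asserted as
"the" original.

## The analytic validation oracle

The solver is validated against a semi-analytic reference
(`sphere_cap_potential`) for a concentric-shell sphere with two
antipodal equipotential cap electrodes: the potential is expanded in odd
zonal harmonics, the interface conditions are folded into per-degree
radial functions by a closed-form shell recursion, and the remaining
mixed boundary condition is resolved *variationally* — the boundary
trace minimizes the Dirichlet energy (an explicit diagonal quadratic in
the Legendre coefficients) subject to the cap constraint, so the
off-cap insulation condition is the natural condition of the
minimization rather than something imposed by collocation weighting.
The injected current is evaluated as the flux through the equatorial
plane, which converges quickly because it avoids the cap-edge
singularity. The oracle shares no code path with the FEM solver (no
meshes, no sparse algebra) and the acceptance suite compares nodal
potentials on a 30-150 degree angular sample of a three-shell sphere at
4 mm edge length, requiring relative L2 agreement within 2%, alongside
exact slab checks and discrete current conservation.

## The thickness algorithm

`thickness_profile` mirrors the normal-vector minimum-distance
procedure: outermost scalp elements within a 10 mm surface ROI are each
measured to the nearest point on the skull boundary surface, a
candidate being accepted only if the direction to its foot point lies
within `angle_tol` (default 45 degrees) of the element's inward surface
normal; the skull foot-point elements are then measured to the CSF
surface, those to the gray-matter surface, and the gray-matter
foot-points to the white matter (cortical thickness). Perpendicularity
is verified at every layer, each layer's normals being re-derived from
that layer's own interface faces. Scalp-to-cortex thickness is defined
as the exact sum scalp + skull + CSF; cortex is reported but excluded
from the aggregate.

One definitional point deserves emphasis: the measurement origin for a
source element is the centroid of its *interface face* (the exterior
face for scalp; the previous layer's foot face when chaining), not the
tetrahedron centroid. A tet centroid sits a quarter of the element
height below the interface, which would bias every layer thin by a
resolution-dependent amount; the face-centroid origin makes the
parallel-plane slab case exact to machine precision and the sphere
phantom accurate to well under half an edge length, and is the reading
of "center of each element" consistent with those two checks.

Remaining conventions: the ROI ball is Euclidean rather than geodesic
(negligible at 10 mm on head-scale curvature); chained source sets are
the unique foot-point elements of the previous layer; nearest-candidate
ties break deterministically to the lowest face index; and loosening or
tightening `angle_tol` between 90 and 30 degrees moves the spherical
estimate by under 2% (checked in the suite).

## The synthetic cohort generator

`simulate_cohort` draws group, age, sex and BMI from truncated normal /
Bernoulli distributions whose moments follow the study demographics
(BMI 25.5 (5.5) / 31.4 (7.4) / 29.1 (6.6) kg/m^2 for controls,
psychosis, relatives; ages ~38-45; male fractions 0.48 / 0.566 /
0.315). BMI truncation is [10, 70] kg/m^2: at these bounds the
truncation bias on the psychosis mean is about +0.04 BMI units, so the
generated moments still reproduce the targets; a floor as high as 15
would bias the mean by a quarter unit. An optional medication sub-model
draws psychosis BMI from a medicated/unmedicated mixture (31.6 (6.3)
vs 28.0 (7.0), prevalence 0.67) instead; it is off by default because
the mixture mean implied by the disclosed-medication subgroups sits
below the whole-group mean, and the group-moment targets take
precedence.

The causal chain is then: scalp thickness = 2.5 + 0.15 * BMI + N(0,
0.5) mm, clamped at 2 mm (the source study reports a strong BMI-scalp
association but no slope in mm per BMI unit, so the link is an exposed
parameter; the default produces ~6-8 mm adult scalps and a ~0.9 mm
group difference); skull, CSF and cortex thicknesses are drawn
independently of group (6 (0.5), 2 (0.3), 3 (0.3) mm), matching the
finding that only scalp and the aggregate differed robustly; and ROI
field strength is a monotone function of scalp-to-cortex thickness
times multiplicative log-normal noise with sigma = 0.06 on the log
scale. That noise level is back-calculated from the reported regression
scale — a group coefficient near -0.007 V/m with SE 0.002 at n = 179 on
fields of ~0.2 V/m implies a residual coefficient of variation around
6% — and with it the generated effect sizes land in the reported f^2
range (~0.05-0.13) at study-scale n.

Fields come either from one FEM solve per subject (`mode = "fem"`,
small cohorts) or from a surrogate calibrated by FEM
(`calibrate_field_surrogate`): a >= 5-point ladder of phantoms with
increasing scalp thickness is solved per montage, and a monotone
Hermite (Hyman-filtered) spline of ROI |E| against scalp-to-cortex
thickness is fitted per montage and hemisphere. A monotone spline
rather than a parametric attenuation law avoids asserting a functional
form the source never states; inputs outside the calibrated range are
clamped to its ends. The suite checks rank agreement between the two
modes on a paired small cohort (pooled Spearman >= 0.9) and that the
calibration ladder itself decreases strictly — the monotone-attenuation
property — in both montages and hemispheres.

What the generator does *not* emulate: cortical folding and subject-
specific montage geometry; any direct group effect on the field beyond
the thickness chain (the default direct path is zero, so full mediation
is the generating truth, and proportions mediated near 100% are
expected); diagnosis subtypes and medication dose; and fat as a
separate tissue. Passing tests therefore demonstrate that the
*machinery* recovers a known causal structure at realistic effect and
noise scales — not that real heads behave like spheres.

## Statistics and mediation

Group comparisons are ordinary least squares of outcome on group
(control = 0), age and sex (male = 1), with Cohen's f^2 computed as the
R^2-increment form attributable to the group term: f^2 = (R2_full -
R2_reduced) / (1 - R2_full) with the reduced model age + sex only. The
sensitivity analysis (`min_detectable_f2`) inverts the noncentral-F
power function with noncentrality lambda = f^2 * N (total-sample
convention); with three predictors this reproduces both printed design
values (0.04 at N = 179, 0.07 at N = 116) at reporting precision, and
the error-df convention is available as an option since the original
software convention is not stated. Demographics use `wilcox.test`
(exact for small samples, normal approximation with ties otherwise),
`chisq.test` on the 2 x 2 sex table, and a one-sample `ks.test` whose
reference is a normal with the sample's own moments by default; a
strict standard-normal mode exists because a reported D = 1 for
variables like age is only attainable against an unstandardized
reference — the package flags this rather than asserting which was
used. Bonferroni families follow the analysis design: 0.05/16 for the
regression family, 0.05/12 for the mediation family.

`mediate` fits linear mediator and outcome models without a
treatment-by-mediator interaction, so a single ACME (= a*b), ADE and
total effect are defined and total = ACME + ADE holds identically; the
suite asserts this per bootstrap draw and checks that the total equals
the plain group-regression coefficient. Uncertainty is a nonparametric
pairs bootstrap (whole subjects resampled, both models refit, 1000
draws by default) with percentile intervals; bootstrap p-values are
2 * min(fraction <= 0, fraction >= 0), floored at 2/n_boot — a
consequence being that corrected-alpha decisions (0.05/12 = 0.0042)
require n_boot >= ~500 for the floor not to censor them, which is why
the pipeline keeps 1000 draws even where unit tests economize to 300.
The full/partial/none classifier implements the reporting rule (full:
ACME significant, ADE not; partial: both; none: ACME not), with alpha a
parameter so either the nominal or the Bonferroni-corrected level can
be applied. Proportion mediated is the point-estimate ratio 100 *
ACME/total; when the two disagree in sign the signed ratio is returned
and flagged rather than silently truncated. Under the double null
(a = b = 0) the product-of-coefficients bootstrap is known to be
conservative, and the suite's calibration check (false-positive rate
at most 7% at alpha = 0.05) reflects that.

## Problem sizes and runtime choices

The suites run at deliberately modest sizes chosen as adequate for
their statistical purpose: phantoms at 6-10 mm surface edge (the onion
construction keeps thin layers resolved regardless), the analytic-
sphere comparison at 4 mm on a 50 mm three-shell sphere, surrogate
calibration on a 6-point ladder per montage, mediation coverage over
200 replicates of n = 500 with 300 bootstrap draws, null calibration
over 500 replicates, and the end-to-end replication over 20 seeded runs
of 150 + 150 subjects with 1000 bootstrap draws. Every stochastic stage
takes an explicit seed, and `run_study` derives all stage seeds from
one master integer so a full study is reproducible from its
configuration object alone.

## Known limitations

Spherical phantoms cannot probe folding-driven field heterogeneity or
electrode-position error; the surrogate collapses four thickness
degrees of freedom into scalp-to-cortex distance (its rank agreement
with per-subject FEM is high but not perfect, as skull and scalp
millimetres are not biophysically interchangeable); P1 elements
under-resolve the field inside the thin, low-conductivity skull at
coarse resolutions (the refinement test quantifies this); the mediation
model assumes sequential ignorability and linear, interaction-free
structural equations, and no sensitivity analysis to those assumptions
is provided; and the Gmsh interface covers ASCII v2.2 tetrahedral
meshes only.
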