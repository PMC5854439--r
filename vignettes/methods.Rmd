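---
title: "Models and methods behind basketmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind basketmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`basketmap` simulates rotor-driven atrial-like electrical activity and
maps it with a virtual multi-electrode basket catheter, so that the
three factors that degrade clinical rotor localization —
electrode–endocardium distance, far-field sources, and inter-electrode
interpolation — can be studied quantitatively on inputs whose ground
truth is known exactly. This vignette records the models, the numerical
choices, and the judgement calls, in enough detail that a reader can
assess what the package's results do and do not demonstrate.

## Cellular electrophysiology

The membrane kinetics are the Courtemanche–Ramírez–Nattel (CRN) human
atrial action-potential model: 21 state variables (V_m, 15 gating
variables, Na⁺/K⁺/Ca²⁺ concentrations and two sarcoplasmic-reticulum
calcium pools), twelve membrane currents in pA/pF, and C_m = 100 pF.
All baseline constants come from the original 1998 publication and are
collected in one table-driven block at the top of `src/crn.cpp`.

Regional electrophysiological heterogeneity enters as dimensionless
multipliers on three maximal conductances (I_to, I_CaL, I_Kr),
producing nine regional variants (RA/PM is the unmodified baseline;
crista terminalis and Bachmann's-bundle variants raise g_CaL; the valve
rings and pulmonary-vein variants raise g_Kr and/or lower g_CaL;
appendage variants lower g_to) — see `crn_region_table()`. Chronic-AF
(cAF) remodeling multiplies, on top of the regional scalars, five
conductances (g_to, g_CaL, g_K1, g_Kur, g_Ks), with different factors
for the right- and left-atrial families of regions
(`caf_remodeling_table()`). The composition is multiplicative by
construction: remodeling is expressed as relative changes and the
regional models are the substrate being remodeled.

Pacing uses 28 pA/pF, 2 ms pulses. The stimulus is applied as an inward
(depolarizing) current; the sign convention is explicit because the
protocols state only a magnitude. APD at a repolarization fraction f is
measured on the last paced beat from the instant of maximal upstroke
velocity to the crossing of `V_rest + (1 − f)·(V_peak − V_rest)`, with
V_rest taken immediately before the final stimulus. The upstroke
reference and the per-beat rest are the package's convention (stable
under diastolic drift); APD conventions in the literature differ at the
few-ms level, and because the late repolarization tail of the control
AP is shallow (~0.07 mV/ms near APD95), a threshold difference of well
under 1 mV moves control APD95 by ~10 ms while leaving the steep-tailed
cAF APDs essentially unchanged. Comparisons of long-AP durations across
implementations should therefore be read with that sensitivity in mind.

Integration is Rush–Larsen for all gates (exact exponential update
toward the voltage-dependent steady state) and forward Euler for V_m
and the concentrations, dt = 0.01 ms for single cells. Halving dt
changes APD95 by well under 1 ms (tested), and 60 versus 120 beats at
one cycle length differ by under 2 ms (quasi-steady state).

## Monodomain tissue solver

Tissue is the monodomain equation ∇·(D∇V_m) = C_m ∂V_m/∂t + I_ion with
no-flux boundaries, where D is the equivalent tensor λ/(1+λ)·D_i under
equal anisotropy ratios (λ = 1 by default). Domains are structured
quadrilateral grids over sheets, annuli (a sheet with a central
non-conducting hole) and cylindrical surfaces (periodic in the
circumferential direction); holes stand in for anatomical orifices.
Diffusion is finite differences with harmonic-mean face conductivities,
which makes no-flux boundaries and non-conducting obstacles natural
(zero-flux faces) and the stencil exactly conservative — the column
sums of the operator vanish, which the source computation below
inherits. Each step splits reaction (Rush–Larsen, with voltage lookup
tables at 0.02 mV resolution rebuilt per dt) from an explicit diffusion
update; the stability bound dt ≤ dx²/(2(Dx+Dz)) is checked at run time.

Tissue defaults are dt = 0.02 ms and, for the shipped scenario,
dx = 0.5 mm. The baseline diffusivity D = 0.1 mm²/ms yields a measured
planar conduction velocity of ≈44 cm/s (control, BCL 500 ms, dx = 0.3,
dt = 0.01) — deliberately at the slow end of the atrial range so that
the chronic-AF wavelength (CV × APD ≈ 4–5 cm) fits the desk-scale
domain and sustains a stable spiral; absolute atrial conductivities vary
widely across hearts and preparations, so only the control-to-cAF
**ratio** is treated as a quantity with external meaning. Combining cAF membrane remodeling
with a 15% conductivity reduction lowers CV by ≈17.8% relative to
control: the √D factor contributes ≈8% and the remodeled membrane
(chiefly doubled I_K1 opposing the foot of the upstroke) the rest.

Two numerical caveats are stated openly. First, at the working
resolution the steep CRN upstroke is marginally resolved, so absolute
CV carries a discretization bias of order 5–10% at dx = 0.3–0.5 mm;
the bias is common mode between conditions and cancels in the CV ratio.
The solver's spatial convergence is verified in a resolved regime
(D = 0.6 mm²/ms: dx 0.3 → 0.15 changes CV by 2.3%, and CV scales as √D
to within 5%). Second, the reaction-only limit reproduces single-cell
traces through the lookup-table path to within ~0.1 mV away from the
upstroke; the table resolution is far below any quantity of interest.

## Forward electrograms

Under equal anisotropy the extracellular potential obeys a Poisson
equation whose source is s = −1/(1+λ)·∇·(D_i∇V_m). The package
evaluates s with the *same* discrete operator as the diffusion step
(discrete consistency: a numerically resting tissue produces exactly
zero total source), assigns each node a volume dx²·thickness (0.75 mm
wall by default), and replaces the torso by an infinite homogeneous
conductor of conductivity σ_b (1 S/m default):
V_e(p,t) = 1/(4πσ_b) Σ_c s_c(t)·vol_c/|p−c|. This one-point-per-cell
monopole quadrature is first order; electrode–source distances are
clamped below dx/2 (logged) to avoid the kernel singularity. A bounded
torso would mainly rescale amplitudes, so EGM amplitudes are treated
throughout as relative quantities (orderings, ratios), never absolute
millivolts; superposition across source masks is exact by linearity,
which is what the far-field masking experiment relies on.

## Phase mapping

Electrograms (and, for the ground-truth reference, V_m itself, so both
maps share one convention) are band-pass filtered at 7–10 Hz — chosen
for rhythms near 9 Hz; the band is a configurable knob for scenarios
with other rates — with a 4th-order Butterworth applied
forward-backward. Zero phase matters: group delay would shift
activation timing and displace every singularity. The filter is seeded
with steady-state initial conditions on odd-reflection padding, and the
Hilbert transform is computed on the full record in the frequency
domain; the first and last 500 ms are trimmed to exclude residual edge
effects. The instantaneous phase is θ = atan2(HT[x], x) ∈ (−π, π]; an
activation (EGM downstroke) crosses 0 from positive to negative phase,
which fixes chirality labels reproducibly.

## Singularity detection, tracking, rotations

For every grid plaquette (or polygonal element) the phase differences
along the oriented boundary are wrapped to (−π, π] and summed. The sum
is an exact integer multiple of 2π — there is no floating tolerance to
argue about — and elements summing to ±2π are singularities of that
chirality. On a simply connected frame the interior charges sum to the
winding number of the boundary phase, which the tests assert exactly on
100 random phase fields. Detections are linked greedily
(nearest-neighbour, same chirality, default link radius 4 mm on basket
projections and 5 mm on tissue, bridging up to 2 and 5 skipped frames
respectively; the linking rule is the package's own, as trajectory
construction is not prescribed by phase-mapping theory). A track's
rotation count is the unwrapped phase excursion, divided by 2π, of a
probe channel a fixed distance (3 elements) from the track centre over
the track's lifetime; tracks with at least one full rotation qualify as
rotors. Rotation counting via a probe ring is robust to electrogram
morphology, unlike activation counting.

## The basket catheter and its projection

The basket is a sphere (default 31 mm diameter) with electrodes at
equal arc spacing (4.8 mm for 8 per spline) along equally spaced
meridians, symmetric about the equator; the published neighbour
distances of the 64-pole device (≈11.7 mm between splines at the
equator, ≈5.4 mm at the outermost rings) emerge from this layout to
within 3–5%. Alternative densities (4×6, 16×16) keep the meridional
span. Electrode signals are interpolated onto a periodic
longitude × arc-latitude chart — 57,600 points by default, 240×240 —
by barycentric-linear interpolation on the triangulated electrode
lattice (fixed diagonal, seam-aware); the pole caps beyond the outer
rings are not interpolated, so circulation centred on a pole appears as
boundary winding rather than as a chartable singularity. Because the
band-pass, the Hilbert transform and the interpolation are all linear,
interpolating the electrode analytic signals is *exactly* equivalent to
interpolating raw electrograms and filtering per grid point; the
package uses the former, cheaper path.

## Classification: TRUE_ROTOR, IMPS, FIPS

A basket track is projected radially (through the basket centre) onto
the tissue surface and matched frame-by-frame against the ground-truth
singularities; a median distance ≤ 10 mm makes it a TRUE_ROTOR.
Unmatched tracks are split by the sequential-activation criterion.
Around the singularity the four lattice electrodes of the containing
cell are examined; activation times are the steepest negative
deflections of the raw unipolar electrograms (the standard convention).
Cycles are anchored on the best-covered electrode's activations, and a
cycle counts as *sequential* when the four delays are consistent with a
single propagating wavefront in either of two forms: a circular
rotation (activation phases strictly monotone around the ring, winding
exactly ±2π — the local-rotor signature) or a sweeping/near-simultaneous
front (all delays within 35% of the cycle — the far-field signature,
since a distant source drives neighbouring electrodes nearly in step at
desk scale). Interpolation artifacts fail both: their surrounding
activations scatter across the cycle. The score is the fraction of
consistent cycles; ≥ 0.8 labels the track IMPS, otherwise FIPS, and
tracks whose neighbourhoods carry too few detectable activations
default to FIPS and are flagged. For four electrodes with random
distinct activation phases spread over the cycle, exactly one third of
orderings pass the rotation branch — the chance level asserted by
enumeration in the tests. Both thresholds (10 mm, 0.8) are
package-defined operationalizations of qualitative descriptions, are
exposed as arguments, and the TRUE_ROTOR share is verified to be
monotone in the match threshold. Anatomical reentry — phase winding
around an orifice or edge with no chartable interior singularity — is
deliberately not counted as false: when matched to ground-truth
winding it would be a true detection; in the shipped cylindrical
scenario it manifests as boundary winding at the top edge.

## The synthetic study and what it does (not) emulate

The shipped `standard_scenario()` is a cylinder of circumference
110 mm and height 60 mm (periodic circumferentially, dx = 0.5 mm),
homogeneous RA/PM cAF membrane with 0.85× conductivity, simulated for
2500 ms at dt = 0.02 ms with 1 ms output cadence; after 500 ms trims
the analysis window is 1500 ms, about twelve rotor cycles. One spiral
wave is seeded by a phase-distribution initial condition — states
sampled along one paced cycle arranged as an Archimedean spiral —
rather than by cross-field S1–S2 stimulation, because on a periodic
domain a half-field S2 necessarily creates a counter-rotating pair,
whereas the study design calls for a single rotor whose distal arm
wraps the cylinder and circulates around the top edge (the
anatomical-reentry analog); the S1–S2 utility is provided and tested on
sheets, where it is the natural choice. A 2-mm ectopic focus near the
bottom edge fires every 110 ms, the far-field pacing train whose
wavefronts persistently collide with the rotor's arm. The resulting
rotor has a cycle length of ≈124 ms (≈8 Hz, inside the mapping band), a
few-mm meander, and survives the whole window — also when the pacing
train is stopped mid-run, which the tests assert as a control. The cAF
substrate is the default because the long control APD cannot sustain a
stable spiral at this domain size (control-condition screening
terminates in wavebreak or collapse), mirroring why remodeled substrate
is the setting of interest.

The aliasing fixture synthesizes electrode signals of an oblique
travelling wave with five cycles around the circumference — beyond the
spline Nyquist limit of the 4- and 8-spline baskets, resolved by 16 —
and a steep axial phase gradient (2.8π across the electrode span). The
geometry is chosen from the enclosure condition for linearly
interpolated unit-amplitude analytic signals: an interpolation triangle
contains a zero of the complex field (hence a spurious singularity
pair) precisely when its three vertex phases span more than a
half-circle with no gap exceeding 180°; at 4×6 the spline/ring phase
steps are (90°, 100.8°) and every cell encloses zeros, while at 8×8 and
16×16 no cell does. The fixture therefore produces FIPS-labelled tracks
at 4×6, none at the higher densities, and a plane-wave tissue ground
truth with no singularity at all — the interpolation-artifact mechanism
in isolation.

The far-field masks exploit exact superposition: restricting the
sources to the rotor-plus-edge-reentry region silences the pacing half
of the domain, and singularities detected over the silent region are
necessarily far-field driven; they classify as IMPS and persist when
electrode density increases, unlike FIPS.

What the generators do **not** emulate: three-dimensional atrial
anatomy and wall thickness, fibre orientation, the heterogeneous torso
volume conductor, electrode contact artifacts and noise, and basket
spline deformation (the geometry is rigid by design). Passing the test
suite therefore demonstrates that the mapping chain behaves correctly
and that the distance/far-field/interpolation mechanisms operate as
described on controlled substrates; it does not calibrate absolute
detection percentages for any clinical anatomy, and the package makes
no claim about those.

## Degenerate inputs and failure behaviour

Unknown regions and conditions are rejected by name; non-finite states
abort the right-hand side; |V_m| > 200 mV aborts integration with the
time and node; conduction block on a strand raises an error rather than
returning zero velocity; an all-zero trace has undefined phase and says
so; phase movies shorter than twice the trim margin are rejected;
masks must be non-empty and are constructed nested; electrodes
penetrating tissue are repositioned radially with a warning; and a
scenario whose spiral is not sustained fails loudly rather than
shipping an empty ground truth.

## Problem sizes

Single-cell protocols integrate one minute of pacing in seconds; the
shipped scenario (26,620 nodes × 125,000 steps) builds in minutes on
one CPU, and each basket mapping run (forward model, 57,600-point
projection, detection, tracking, classification) takes tens of
seconds. These sizes were chosen so the full study — scenario, three
placements, three densities, masking and aliasing experiments —
completes comfortably in a single sitting.
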