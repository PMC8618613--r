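---
title: "Methods: structure and wrinkle mechanics of undulated surfactant monolayers"
author: "undulayer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure and wrinkle mechanics of undulated surfactant monolayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(undulayer)
```

## The system and the observables

Saponins such as escin form unusually elastic adsorption layers at the
air–water interface.  At dense packing (≈ 0.49 nm² per molecule) the layer
does not stay flat: to preserve the preferred mutual orientation of the
rigid hydrophobic aglycones, it buckles into a sinusoidal undulation whose
period is comparable to — and can exceed — the lateral box.  This package
implements the analysis chain used to characterise such layers from
coordinate trajectories:

1. hydrogen-bond counts and their relaxation toward a plateau,
2. mass-density profiles, the equimolecular dividing surface, peak widths,
3. molecular tilt, its histogram, the rotational order parameter, and the
   correction of tilt for the local slope of the undulated surface,
4. in-plane and 3D radial distribution functions of a reference aglycone
   atom,
5. extraction and sine-fitting of the surface undulation, and
6. the thin-elastic-sheet estimates linking interfacial rheology to the
   layer's flexural rigidity and wrinkle wavelength.

Internal units are nm / ns / amu everywhere; conversions happen only at
file boundaries (PDB is Å on disk) and inside the elasticity chain (SI).

## Frames, roles, and the synthetic generator

Analyses consume a `monolayer_frame`: atoms with coordinates, masses,
molecule ids, and a semantic *role* drawn from a closed set
(`aglycone_base`, `aglycone_tip`, `donor`, `acceptor`, `hydrogen`,
`water_O`, `water_H`, `other`).  Roles are attached at read time by a
`rolemap` — a function from (residue name, atom name) to role and mass —
so no topology or bond perception is ever needed.  Coordinates are *not*
wrapped into the box on read: undulation analysis needs unwrapped z, and
each analysis applies lateral minimum image itself where appropriate.

Since μs-scale trajectories of these systems are not generally available,
validation rests on a generator with analytic ground truth.  A
`layer_spec()` places `n_molecules` surfactant proxies on a jittered square
lattice in a box of side `sqrt(n * area_per_molecule)`; the base atom
follows `z(y) = y0 + A sin(2πy/B + C)` plus Gaussian noise; the molecular
axis (base → tip, pointing into the water, so an upright molecule reads a
tilt of 180°) is rotated away from the local analytic surface normal by a
sampled tilt angle, leaning azimuthally *with* the surface slope; five
inert beads along the axis complete the 1101-amu molecular mass.  A chosen
fraction of molecules has its donor moved into ideal H-bond geometry
(0.28 nm, collinear hydrogen) with a lattice neighbour's acceptor, and the
true bond list is returned.  Water fills the region between a flat lower
free surface at `y0 - thickness` and the undulated upper surface, by
rejection sampling so the density is uniform under the wave; the default
thickness (6 nm) exceeds the default amplitude (2.1 nm) so that a genuine
bulk region survives below the troughs.  Defaults are the study conditions
of the dense escin layer the generator emulates: 441 molecules at
0.49 nm² (box 14.70 nm), wave A = 2.1 nm, B = 16.6 nm, C = −0.5,
y₀ = 8.0 nm, tilt to the local normal 75° ± 20° (the corrected tilt of the
real layer is ≈ 105° ± 20°, i.e. 75° away from upright), water at
997 kg/m³ (293 K), base-atom z-noise 0.3 nm.

The generator derives independent RNG streams from one seed (placement,
z-noise, tilt, bond selection, water, per-frame jitter), so changing one
knob never shifts unrelated draws, and the same seed is bit-reproducible.
What the generator does **not** emulate: real molecular shape, head-group
flexibility, forces or dynamics.  Frames are statistical stand-ins, so a
passing test demonstrates the correctness of the *analysis*, not the
physics of any particular simulation.

## Hydrogen bonds

A donor–hydrogen–acceptor triple counts as a bond when the donor–acceptor
distance (lateral minimum image; z non-periodic because of the vacuum gap)
is ≤ 0.35 nm and the hydrogen–donor–acceptor angle at the donor is ≤ 30° —
the convention of common MD analysis tools, both cutoffs configurable.
Hydrogens are attached to the nearest donor-capable atom of their own
molecule; a `donor`-role atom with no hydrogen in its molecule is an error.
Candidate pairs come from a lateral cell list; the test suite proves the
cell list equal to a brute-force all-pairs oracle on many random frames,
and checks monotonicity (tightening either cutoff never adds bonds) and
invariance under rigid translations and periodic shifts.  Intramolecular
pairs are excluded from the headline surfactant–surfactant count and
reported separately when requested.

Relaxation is quantified on block averages (`block_average`): blocks are
anchored at t = 0 and a trailing block is kept only if the series reaches
to within one sampling interval of its end, which keeps per-block
statistics comparable and makes the operation invariant to feeding the
series in chunks.  `detect_plateau` returns the start of the earliest
suffix of ≥ 3 blocks whose means all lie within a relative tolerance
(default 2%) of the suffix mean.  For a saturating-exponential relaxation
with time constant τ this lands near the analytic 95%-settling time
τ·ln 20, which is how it is tested (τ = 150 ns over 1 μs, plateau at 15.3
bonds per molecule — the scale of surfactant–water hydration — gives an
onset within 2τ of ≈ 450 ns).

## Density profiles and the dividing surface

Per-bin density is (mass in bin)/(Lx·Ly·Δz) in kg/m³, averaged over frames,
with SDs across 50-ns blocks when requested; atoms are binned at their
actual z, so material lifted into the vacuum gap is counted where it sits.
Mass conservation (profile integral = component mass) holds for every
binning and is asserted to 0.1%.

The equimolecular dividing surface uses the Gibbs construction for a slab
analysed at its upper interface: bulk density is the mean over the 1-nm
window with the smallest mean |gradient| among windows at least half as
dense as the water maximum (a window whose SD exceeds 5% of its mean means
there is no identifiable bulk plateau — the analysis refuses rather than
guesses, which single noisy frames at fine binning can trigger; average
more frames or widen the bins).  Above that window's upper edge z_b the
EDS is `z_e = z_b + M_above/ρ_bulk`, the height at which the integrated
water deficit below equals the excess above.  This is exact for a step
profile and lands on the centre of any symmetric (error-function) profile
to within one bin.

"Half-width" of a component peak is implemented as FWHM/2 with the
half-maximum crossings interpolated linearly between bins — the standard
reading when no definition is given; for a Gaussian peak it equals
1.1774σ.  Two equal non-adjacent maxima or a peak running into the profile
boundary are refused.

## Tilt, order parameter, and the slope correction

Tilt α is the angle between the aglycone vector (tip − base) and +z, folded
into [0°, 180°]; the axis convention (tip into the water) puts upright
molecules near 180° and flat ones at 90°.  The rotational order parameter
is OP = ⟨cos(180° − α)⟩ over molecules and time, block-averaged over 50-ns
segments or per molecule over a window; OP is 1 for a perfectly upright
layer, 0 for isotropic.  Because OP is a plain average, per-block values of
equal blocks average exactly to the global value — asserted in tests.  (No
second-rank nematic P₂ is computed; the first-rank polar average is the
statistic of interest here.)

On an undulated layer, part of the measured tilt is just the local slope of
the surface.  The slope is obtained by fitting a straight line to base-atom
z vs y inside the central half of a monotonic wave segment (between
consecutive extrema of the fitted sine — a window containing an extremum is
refused), and reported as arctan|dz/dy|.  The scalar correction then
shifts the mean tilt by this slope angle.  One subtlety is intrinsic to
folded angles: a scalar α in [0°, 180°] has lost the rotational sense of
the molecular lean relative to the surface slope, so the slope can either
*add to* or *subtract from* the local tilt.  `corrected_tilt()` therefore
exposes both senses: `"opposing"` (default) subtracts the slope from the
mean tilt — the arithmetic appropriate when the lean opposes the surface
inclination, e.g. a layer at mean tilt 142° over a 37° slope corrects to
105°; `"aligned"` adds and folds — appropriate when molecules lean with
the slope, as the synthetic generator builds them, where it correctly
returns upright (180°) molecules on every segment while the raw tilt
varies by tens of degrees along the wave.  For work where the scalar
ambiguity matters, `local_tilt_angles()` computes each molecule's angle to
the local normal of the fitted wave directly and has no such ambiguity.

## Radial distribution functions

Both RDFs histogram pair distances of the reference aglycone-base atoms
with lateral minimum image.  The 2D variant uses (x, y) only — all
reference atoms projected to one plane — and normalises by the ideal-gas
annulus count at the mean areal density, so uniform random placement gives
g(r) = 1 (verified to 2% at ≥ 10⁵ pairs).  The 3D variant uses full
distances and normalises by the whole-box volumetric density, the
convention of common MD tools; in slab geometry this makes g(r) = Lz/(2r)
for an ideal slab thinner than r, dipping below 1 once r > Lz/2 — the
documented depletion, tested against that closed form.  Defaults
dr = 0.02 nm, r_max = 4 nm (r_max may never exceed half the lateral box).

## Undulation extraction and sine fit

Per block, the per-molecule time-averaged base-atom positions trace the
surface.  Smoothing to a "middle line" is by binned means: the lateral
axis is split into n equal bins (default 50) over [0, L), each occupied
bin contributing its mean z at the bin centre.  Binned means are
deterministic and parameter-light; the aggregation error for a smooth wave
is bounded by curvature·w²/8 per bin, which the tests assert.  An
automatic axis mode picks the lateral axis with the larger binned-line
variance for generated data where the wave direction is configurable.

The sine `z(y) = y0 + A sin(2πy/B + C)` is fitted by Levenberg–Marquardt
least squares with multi-start initialisation: A₀ = (max−min)/2,
y₀ = mean, period candidates from the dominant discrete-Fourier mode of
the resampled line plus the box length, and 8 coarse starting phases; the
best-converged start wins and the result is canonicalised to A ≥ 0,
C ∈ (−π, π] (canonicalisation is idempotent: refitting the fitted curve
reproduces the parameters).  B is deliberately *not* constrained by the
box — the physical wave can span more than one periodic cell, and the
wave-to-box ratio B/Lᵧ is a headline output (≈ 1.13 for the default
generator wave, 16.6/14.7).  A perfectly flat line is reported as A = 0
with the period flagged unidentifiable instead of failing.  Each block is
fitted independently; no initialisation is shared across blocks.
Recovery contracts verified in the tests: exact samples to 0.1%; the full
generator pipeline (lattice → extraction → binning → fit) to 1% over
A ∈ [0.4, 2.5] nm, B ∈ [4, 20] nm at zero noise; with 0.3-nm Gaussian
z-noise, median recovery over 20 seeds within 5% (A) and 3% (B).

## The elasticity chain

From the interfacial shear modulus G′_S and dilatational modulus G′_D
(N/m) and the layer thickness h:

- ν = G′_D/(2G′_S) − 1 (values outside (0, 0.5) warn as physically
  unusual),
- Y_s = 2G′_S(1 + ν) — algebraically identical to G′_D, asserted as an
  invariant,
- Y = Y_s/h (Pa), the pseudo-bulk Young's modulus,
- D = Y·h³/(1 − ν²) (J), also reported in units of k_BT
  (k_B = 1.380649×10⁻²³ J/K, default T = 293 K),
- λ = 2√π (D/σ)^¼ L^½, the wrinkle wavelength for surface tension σ and
  sheet length L.

The rigidity is implemented in the divided form D = Yh³/(1−ν²): on the
measured escin inputs (0.057 N/m, 0.165 N/m, 2.6 nm) it gives
D ≈ 1.39×10⁻¹⁸ J ≈ 345 k_BT, the self-consistent value of this parameter
set, whereas the product form Yh³(1−ν²) gives ≈ 8.9×10⁻¹⁹ J.  The
classical plate-theory factor 1/12 is likewise not part of this
parameterisation; `classical = TRUE` applies it for comparison with plate
formulas.  The chain composes the five steps with no intermediate
rounding.  No numeric λ is quoted by default because σ and L are external
inputs; λ is validated by its closed form and scaling laws (λ doubles when
L quadruples).

## Problem sizes and determinism

The test suite runs entirely on generated data at desk scale: single
frames of 100–441 molecules, trajectories of up to 40 frames, 50-frame
batches for the H-bond oracle, 20 seeds for the noisy fit study; the whole
suite completes in a few minutes on one core.  All randomness flows from
fixed seeds, and every expected value is either a closed form, an
independent brute-force oracle, or generator ground truth.

## Limitations

- The generator's surfactant is a 10-site proxy; absolute density-profile
  shapes (e.g. the narrow surfactant peak of a thin rigid proxy) are not
  comparable to chemistry-resolved layers, whose peaks are broadened by
  head-group flexibility and submergence.
- The scalar slope correction is sign-ambiguous by construction (see
  above); conclusions that depend on the sense should use
  `local_tilt_angles()`.
- The sine fit describes a single dominant mode; no height-field spectral
  analysis (bending modulus from ⟨|h_q|²⟩) is attempted.
- Plateau detection assumes block means with stationary noise; strongly
  heteroscedastic series may need a custom tolerance.
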