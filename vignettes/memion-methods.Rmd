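---
title: "Models and methods behind memion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind memion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memion)
```

memion analyses how amphiphilic ions — benzalkonium-like quaternary-ammonium
cations and the anionic detergent SDS — organise in phosphatidylcholine
bilayers with and without cholesterol, and models the planar-bilayer
electrostatics experiments used to quantify their adsorption. This vignette
explains the models, the conventions, the tunable parameters, and the design
choices where the design was genuinely open. Nothing here reports a number
that the test suite or `scripts/acceptance.R` does not itself compute.

## Geometry conventions

All analyses assume a flat bilayer whose average plane is perpendicular to
the third coordinate axis (Oz). Units are fixed throughout: nm, ns, degrees,
elementary charges, mV. Boxes must be orthorhombic; minimum-image arithmetic
is then exact, and triclinic input is rejected rather than silently
approximated.

The membrane centre of a frame is the mean z of the lipid phosphorus atoms.
This is a choice: "membrane centre" could equally be the lipid centre of
mass, and `compute_charge_profile(center_on = "lipid_com")` exposes that
alternative. The phosphorus mean was preferred because the headgroup planes
are what the charge profile and the leaflet assignment are anchored to, and
because it is robust to tail-length asymmetries.

A molecule's leaflet is decided by the z of its reference atom (quaternary
nitrogen, sulfate sulfur, cholesterol oxygen, or lipid phosphorus, in that
priority) relative to the centre. The **outward normal** of the upper
leaflet is +Oz and of the lower leaflet is −Oz. Using per-leaflet outward
normals (rather than a global +Oz) is what makes the pooled angle
distributions of a system with ions in both monolayers unimodal; with a
global axis the same physical orientation would read as `x` in one leaflet
and `180 − x` in the other.

## Orientation angles

For each surfactant molecule, two vectors are built after unwrapping the
partner atoms by minimum image relative to the charged anchor:

* `h`, from the quaternary nitrogen to the carbon in the *para* position of
  the aromatic ring (cationic ions only — SDS has no ring);
* `t`, from the charged anchor (N⁺, or S for SDS) to the terminal carbon of
  the alkyl tail.

The orientation is summarised by `eta = angle(n, h)` and
`theta = angle(n, t)` against the leaflet's outward normal `n`, both in
[0°, 180°]. A molecule lying head-out has small `eta`; a strongly bent ion
with the ring buried under the headgroups has `eta` well above 90°. The
angle between the ring arm and the tail is approximately `theta − eta` for
near-coplanar arms, which is why a bent conformation reads as
`eta ≈ 130°, theta ≈ 150°`.

Angle densities are normalised histograms (per-degree probability density,
integral 1 over [0°, 180°]). The default 2° bin resolves ≈20° features
without histogram noise; the mode is reported as the bin centre of maximal
density. Note that for wide unimodal distributions the histogram mode is a
noisy statistic — the density within a few degrees of a von Mises mode at
concentration κ = 8 is flat to ~1%, so mode estimates at moderate sample
sizes scatter by several degrees even when the density estimate itself is
accurate. Tests therefore constrain the mode with a simulation-calibrated
bound and additionally require near-maximality of the density at the true
mode.

## Charge-density profiles

The bilayer is decomposed into layers perpendicular to Oz. For grid point
`z` the layer `(z − dz, z + dz]` collects the partial charges of each named
atom group; dividing by the layer volume (box cross-section × 2dz) and
averaging over the analysis-window frames gives a density in e/nm³. Each
frame is recentred on the phosphorus mean first, so slow drift of the whole
membrane does not smear the profile. The grid defaults to ±3.5 nm in
0.1-nm steps.

The layer half-width `dz` is exposed separately from the grid step because
the two are logically independent: `dz = step/2` (the default) tiles the
slab, and then each group's integrated density equals its total charge in
the slab exactly — a conservation law the tests assert to 1e-10 e. Larger
`dz` gives overlapping, smoothed layers; normalisation is always per actual
window width, so amplitudes remain densities, but the integral then
multiple-counts charge and the conservation identity applies only to the
tiled case.

Charges are binned as points at the atom position, with no spreading: the
profile is defined as a per-layer sum, and any smoothing should be a visible
choice (via `dz`), not an implicit one.

Peak extraction scans for discrete local extrema above a noise floor,
defaulting to 3× the median absolute density over the outermost 1 nm of the
grid at both ends — a region that contains only water/ions in any sane
membrane system and therefore estimates the background. The separation of
the two dominant negative extrema of the lipid-phosphorus group is the
phosphate peak-to-peak distance, a standard bilayer-thickness proxy: ≈3.6 nm
for a fluid PC bilayer, growing by ≈0.8 nm when cholesterol thickens both
leaflets by ≈0.4 nm.

## Cholesterol clustering and plunge events

Two cholesterol molecules are clustered when their hydroxyl oxygens are
closer than 0.7 nm under the 3D minimum-image metric; cluster sizes are the
connected components of the resulting graph, computed per frame and
averaged over the window. Size-1 components (isolated molecules) are
tabulated too, and the summary reports the mean cluster count both with and
without them, since either convention is defensible. Clustering is done
across both leaflets by default — at 0.7 nm an O–O contact across an intact
bilayer is geometrically near-impossible, so the choice rarely matters —
with a `per_leaflet` switch for the strict variant. The cutoff must be
below half the smallest box edge, the validity bound of minimum image.

A plunge event is an excursion of a cholesterol oxygen into the midplane
band `|z − centre| < 0.3 nm`; events are kept when the dwell (time between
the first and last frame inside the band) reaches 1 ns. Dwell is therefore
quantised by the frame stride, and halving the stride changes estimates by
at most one stride — a reparameterisation consistency the tests check. The
band half-width and dwell threshold are package defaults chosen to separate
genuine midplane residence from headgroup-region fluctuations (lipid
headgroup planes sit ≈1.8 nm from the centre, thermal z-fluctuations are
well under 0.3 nm); excursions are rare, qualitative events, and both
parameters are exposed. `reached_interface` additionally flags whether the
oxygen came within half the band width of the exact midplane.

## The electrostatic measurement model

The boundary potential of one monolayer is the sum of the diffuse-layer
surface potential and the dipole potential. The model identifies measured
*changes* entirely with the diffuse layer: when adsorbed ions neither cross
the membrane nor reorganise the headgroup dipoles, the capacitance-based
and carrier-based methods report the same change, and a dipole term would
be indistinguishable anyway. This is an explicit modelling assumption, not
a law.

**Grahame / Gouy–Chapman.** For a 1:1 electrolyte of concentration c at
temperature T,

&psi;₀ = (2RT/F) · asinh( &sigma; / √(8 &epsilon;₀ &epsilon;ᵣ R T c) ),

with σ the surface charge density. The implementation works in e/nm² and mV
and inverts the relation in closed form. Its small-σ slope is the
Debye–Hückel capacitance 1/(ε₀εᵣκ), an identity the tests verify to 1%
below 10 mV. No Stern layer and no finite-ion-size corrections are
included.

**Self-consistent Langmuir adsorption.** At bulk concentration c the
surfactant concentration at a surface already charged to ψ₀ is
`c_s = c·exp(−zFψ₀/RT)`; coverage follows the Langmuir isotherm
`Γ = Γmax·K·c_s/(1 + K·c_s)`; the surface charge is `σ = zΓ`; and ψ₀ must
again satisfy the Grahame equation. The fixed point is solved by damped
iteration (damping 0.5, tolerance 1e-6 mV, hard cap 1e4 iterations with the
final residual reported on failure). The electrostatic feedback matters: a
cationic surfactant repels further cations, so the self-consistent curve
lies below the naive Langmuir–Grahame composition (`feedback = FALSE`
reproduces the naive one). `ΔΦ_b = ψ₀` is the model output; for an anionic
surfactant the curve is the exact sign mirror.

**Fitting.** `fit_adsorption` estimates (K, Γmax) by Levenberg–Marquardt on
the log parameters — both are positive scale parameters, and the log
transform makes the optimisation unconstrained and better conditioned.
Start values come from the half-saturation concentration and the
Grahame-inverted plateau. A flat curve leaves both parameters
unidentifiable; the fit is flagged rather than forced. A practical
identifiability point, verified by simulation during development: the
concentration series must span the isotherm (well below half-saturation
through near-saturation), otherwise K and Γmax trade off along a ridge and
no estimator will pin them to 10%.

**Inner field compensation.** Electrostriction thins a membrane under an
internal field, so the capacitance is a parabola in the applied voltage,
`C(U) = C₀(1 + α(U − Φ_in)²)`, minimal exactly when the applied voltage
compensates the intramembrane potential difference. The vertex is obtained
from an ordinary quadratic least-squares fit (exact on noise-free input),
with the vertex standard error from the delta method. Scans must bracket
the minimum; a monotone or non-convex scan is a range error, not a number.
Higher-order electrostriction terms are ignored. The synthetic scan default
(±100 mV around the vertex in 2-mV steps, 1% multiplicative capacitance
noise, α = 2×10⁻⁵ mV⁻²) is chosen as an instrument design: a scan must
resolve potentials at the mV scale to be useful, and this grid yields a
vertex standard error near 0.5 mV.

**Nonactin conductance.** The carrier's conductance reports the
electrostatic barrier for its cation complex; an added boundary potential
ΔΦ changes it by a Boltzmann factor, so `ΔΦ_b = (RT/F)·ln(G₀/G)` (25.42 mV
per e-fold at 295 K). Sign convention: positive adsorbed charge raises the
barrier and lowers G, giving positive ΔΦ_b. The relation is the standard
barrier model adopted here explicitly, since only the measurement principle
— not a formula — is usually stated with such data.

## The synthetic-data generator

The generator emulates the *statistical structure* of a bilayer simulation,
not its physics: no force field, no dynamics. It exists so that every
analysis stage can be tested against known ground truth.

* Lipids sit on a jittered square lattice at z = ±`leaflet_z` (default
  1.8 nm, the fluid-PC phosphate plane; 2.2 nm emulates the
  cholesterol-thickened state), phosphorus charge −1 e, with the nitrogen
  +1 e placed 0.1 nm further out — reproducing the inner-negative /
  outer-positive peak pair of a zwitterionic PC profile. The default 101
  lipids per leaflet matches a ~200-lipid simulation cell at
  0.65 nm²/lipid.
* Surfactants realise their prescribed orientation geometrically: per
  molecule, `eta` and `theta` are independent draws from a von Mises
  distribution about (η₀, θ₀) with concentration κ, folded into [0°, 180°]
  (a polar angle is defined only up to reflection), and the para-carbon and
  terminal-carbon positions are constructed at exactly those angles from
  the anchor with uniform azimuths, respecting the leaflet's outward
  normal. κ = 8 (circular SD ≈ 20°) reproduces the width of a
  cholesterol-ordered angle distribution; smaller κ emulates the broad
  cholesterol-free case. Folding shifts the realised mean slightly below a
  mode at 150° (≲1.5° at κ = 8) — visible only against 3-SE recovery
  bounds, and accounted for in how the tests pool estimates.
* Cholesterol oxygens follow a Thomas clustered point process per leaflet
  (Poisson parents, Gaussian offspring of scale `offspring_sigma`), giving
  cluster-size distributions a tunable, analytically understood target:
  tighter offspring scatter yields larger clusters at the 0.7-nm criterion.
* Frames add i.i.d. Gaussian jitter (default σ = 0.05 nm) to every
  coordinate. This stands in for thermal roughness and broadens profiles
  realistically, but — deliberately — there is no lateral diffusion, no
  collective undulation, and no orientational dynamics: a molecule keeps
  its drawn orientation for the whole trajectory. Passing recovery tests
  therefore demonstrates correctness of the geometry and statistics
  pipeline, not robustness to correlated membrane dynamics.
* Everything downstream of the seed is deterministic, and the emitted
  manifest records every realised draw, so tests can compare analysis
  output against ground truth molecule by molecule.

Measurement curves are generated from the adsorption model plus additive
Gaussian noise (default 2 mV, the scale of symbol-sized error bars on
boundary-potential plots), with one capacitance scan per concentration
whose vertex sits at the noisy potential. The example ground truth
(K = 3×10⁶ M⁻¹, Γmax = 0.2 nm⁻²) produces tens of mV across sub-µM
concentrations, the scale such experiments report. End-to-end validation
averages four replicate simulated experiments per concentration, the
mid-range of typical experimental practice of averaging 3–6 measurements.

## Numerical choices and degenerate inputs

* Angles are computed via `acos` of a clamped cosine; zero-length anchor
  vectors (coincident atoms) skip the record with a warning rather than
  propagating NaN.
* Histogram bins are half-open `(a, b]` with angle 0 assigned to the first
  bin; layer windows are half-open the same way, so tiling never
  double-counts.
* The Grahame pair uses `asinh`/`sinh` directly — numerically stable at
  both tiny and large σ; the round trip is exact to 1e-10 relative.
* Peak ties (plateau edges) count once: strict inequality on one side,
  non-strict on the other.
* Empty atom groups give a zero profile with a warning; an all-zero profile
  yields an empty peak set; a flat potential curve yields an unidentifiable
  flag — degenerate inputs produce typed, explained outcomes, not numbers.

## Problem sizes

The shipped tests and the acceptance script run, per invocation: a
500-surfactant / 100-frame recovery system, a 202-lipid / 50-frame profile
system, 200 random cluster configurations of up to 60 molecules, 200-replicate
Monte-Carlo loops for the IFC and adsorption estimators, and a 40-replicate
end-to-end closure loop — sizes chosen so the full statistical battery
completes in about a minute on one CPU while keeping Monte-Carlo standard
errors comfortably below the tolerances being asserted.

## Known limitations

* GRO and multi-MODEL PDB are the supported trajectory formats; compressed
  binary trajectories (XTC/TRR/DCD) must be converted first (e.g.
  `gmx trjconv`).
* The electrostatic model has no Stern layer, no ion-size corrections, no
  dipole-potential term, and no kinetics; it reconstructs equilibrium
  diffuse-layer curves only.
* The synthetic generator's independence assumptions (no lateral
  correlations between molecules, frame-i.i.d. jitter) understate the
  autocorrelation of real trajectories; effective sample sizes in real data
  are smaller than the record count, and error bars computed from real
  frames should account for that.
* Orientation analysis requires explicit role-map entries; the package
  never guesses which force-field atom is "the terminal carbon" of a
  branched tail.
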