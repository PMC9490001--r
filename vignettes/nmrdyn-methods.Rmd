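---
title: "Methods: multi-timescale NMR backbone dynamics in nmrdyn"
author: "nmrdyn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-timescale NMR backbone dynamics in nmrdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nmrdyn)
```

This vignette documents the models, assumptions, numerical choices and
limitations behind each stage of the pipeline. It states no empirical
result that the test suite or `scripts/acceptance.R` do not themselves
compute.

## Scope and design

The package analyses protein backbone dynamics on three timescales with
three observables: ¹⁵N relaxation (ns), residual dipolar couplings
(µs), and hydrogen/deuterium exchange (ms and slower). Because
experimental data of this kind are typically not deposited alongside
publications, every stage has a seeded generator producing inputs with
the statistical structure the stage assumes, plus the generating truth;
correctness is demonstrated by parameter recovery rather than by
comparison with any particular experimental data set. All pseudo-random
work takes an explicit seed, fanned out to per-generator streams by a
fixed rule (`seed * 16 + stream-id`, folded below 2³¹).

## Nanosecond stage: relaxation and model-free analysis

**Forward model.** `lipari_szabo_rates()` evaluates R₁, R₂ and NOE for
an amide ¹⁵N–¹H pair from the two-Lorentzian model-free spectral
density (order parameter S², internal time τ_e, global tumbling τ_m)
inserted into the standard dipolar + CSA expressions. Constants are the
conventional model-free defaults — r(N–H) = 1.02 Å, ¹⁵N CSA −160 ppm,
standard gyromagnetic ratios — at a default proton frequency of
700 MHz. Isotropic tumbling is assumed throughout; no diffusion-tensor
anisotropy is modelled.

**Decay fitting.** R₁/R₂ intensity decays are fit as I(t) = A·e^(−Rt)
by Levenberg–Marquardt with a log-linear start and (when per-point
errors are present) 1/σ² weights. The fitted rate is invariant under
intensity rescaling. Degenerate (constant) curves are rejected.

**Exchange flagging and τ_m.** Residues in slow conformational exchange
inflate R₂/R₁. `flag_exchange_residues()` flags ratios above
trimmed-mean + k·trimmed-SD with 10% trimming and k = 1.5 by default —
values chosen as a robust default since no universal threshold exists.
`estimate_tau_m()` inverts the rigid-limit isotropic R₂/R₁ relation
(strictly increasing in τ_m over the physical range, so the root is
unique) for the mean ratio of unflagged residues, with an optional
seeded bootstrap for the error.

**Model selection.** Each residue's (R₁, R₂, NOE) triple is fit under
the four standard model-free parameterisations {S²}, {S², τ_e},
{S², R_ex}, {S², τ_e, R_ex} by bound-constrained quasi-Newton
minimisation of χ² from three multi-starts. Selection uses plain AIC
(χ² + 2k). The small-sample corrected AICc is the more common default
elsewhere, but with n = 3 observations per residue its correction term
2k(k+1)/(n−k−1) is undefined for the 2- and 3-parameter models, so AIC
is the defensible choice at single-field data. Residues whose best χ²
exceeds a configurable threshold (default 11.3, the 0.99 χ²₃ quantile)
are flagged rather than dropped. S² errors come from the numerical
Hessian of χ² at the optimum; they are unreliable when the optimum sits
on the S² = 1 boundary and are reported as NA there.

**What recovery tests show.** The generator produces Lipari–Szabo-exact
triples with relative Gaussian noise (default 3%, a typical
relaxation-measurement precision). Recovery at that noise level
demonstrates the fitter and the selection logic; it does not probe
model misspecification (anisotropic tumbling, multi-field
inconsistencies, noise correlations) that real data may carry.

## Microsecond stage: RDCs, tensors and ensemble refinement

**Back-calculation and fitting.** D_calc = D_max(pair) · vᵀS v, with S
the traceless symmetric Saupe matrix and D_max computed from physical
constants at r(N–H) = 1.02 Å and r(C′–N) = 1.329 Å. C–N couplings are
kept in native Hz (not rescaled onto the N–H scale) and weighted by
their errors where present. `svd_fit_tensor()` solves the 5-component
linear problem by SVD with a condition-number guard; the Q factor
follows the rms(ΔD)/rms(D_exp) convention. The steric
(shape-alignment) predictor uses the anisotropic part of the heavy-atom
gyration tensor scaled by a configurable magnitude — a deliberately
simple geometric surrogate; the charge contribution of full
alignment-prediction models is out of scope.

**Replica-averaged restraint.** The pseudoenergy
E_rdc = α Σ w_i (⟨D_calc,i⟩_M − D_exp,i)² averages couplings over M
replicas before comparing with experiment, so heterogeneous ensembles
can satisfy data that no single structure fits. Gradients are analytic
in every replica's coordinates with the tensor held fixed — matching
the fitted-tensor restraint scheme in which tensors are refit at a
stride (default every 100 accepted moves, configurable) and frozen in
between; tensor-coordinate derivatives are deliberately omitted.
Multiple alignment media are handled with one tensor per medium.

**Sampler.** Explicit-solvent molecular dynamics is replaced by a
desk-scale Metropolis Monte-Carlo sampler over toy potentials: harmonic
bonds and angles (reference values from the input geometry), periodic
torsion restraints on φ/ψ/ω, and a soft excluded-volume term between
sequence-distant CA atoms. Moves mix single-atom Gaussian displacements
with φ/ψ torsion pivots (rotation of the downstream chain about the
bond axis, which preserves bonded geometry and mixes large-scale
conformation efficiently). The annealing schedule is a deterministic
triangular temperature ramp per cycle (defaults: 50 cycles between
310 K and 500 K, first 20 discarded as burn-in, extraction window the
final 1/8 of each cycle, 10,000 steps per cycle standing in for the
original 8 ns/cycle); the restraint force constant is ramped up gently
over 10 equilibration stages (linear multipliers 0.1…1 — the exact
profile of the original protocol is unspecified, so a linear ramp is
adopted). Trajectories are bit-reproducible given a seed.

**The two-state benchmark.** `two_state_rdc_benchmark()` freezes the
conditions of the replica-averaging experiment: a 12-residue hinged
helical chain whose only soft degree of freedom is the hinge ψ; a
noiseless N–H + C–N coupling target computed as the 50:50 average of
two conformers at ψ = 160° and −90° under a known tensor; refinement
with that tensor fixed (the synthetic analogue of computing the tensor
from structure rather than fitting it to the data, which would hand a
single structure five extra degrees of freedom); a stiff potential
(k_bond 3000, k_angle 2000, k_torsion 60 kJ/mol-units) so that the
restraint cannot buy agreement by distorting local geometry; replicas
initialised overdispersed in the hinge (ψ ~ U(−120°, 180°)), standard
practice for ensemble samplers that must populate several basins; and a
scaled-down 9-cycle × 6000-step schedule chosen so the experiment
equilibrates at desk scale. Ensemble quality is scored as the median
over post-burn-in cycles of the Q factor of the window- and
replica-averaged couplings — the quantity the restraint actually
controls; single-snapshot Q values are inflated by thermal orientation
noise and are reported separately in the trajectory log. Under these
conditions an M = 8 ensemble splits between the two hinge basins and
reaches low Q, a single restrained replica cannot (it is pulled to a
compromise structure), and the α = 0 control shows no improvement.

## Millisecond stage: hydrogen exchange

The two-state scheme closed ⇌ open → exchanged gives
k_obs = k_op·k_int/(k_cl + k_int); the EX2 limit k_cl ≫ k_int reduces
this to k_op·k_int/k_cl, making logP = log₁₀(k_int/k_obs) a direct
report of the opening equilibrium. The package treats EX2 as an
assumption to be respected by the generator (k_cl = 1000·k_int by
default) and checked algebraically (the limit agrees with the exact
expression to 1% whenever k_cl/k_int ≥ 100); experimental EX1/EX2
discrimination (e.g. by mass spectrometry) is out of scope.

Intrinsic rates come from bundled poly-DL-alanine reference constants
with nearest-neighbour side-chain corrections, acid/base/water terms
and Arrhenius temperature factors (activation energies 14/17/19
kcal/mol, reference 293 K), in the standard community parameterisation;
the file `inst/extdata/intrinsic_rate_factors.tsv` carries provenance
comments. The solvent ionisation constant is not itself
temperature-corrected — the Arrhenius factor on the base term absorbs
the dominant temperature dependence — and pD values are used as direct
glass-electrode readings without isotope correction. Both choices are
conventions; they cancel in any analysis that generates and recovers
with the same constants, and they affect absolute logP values by a
residue-independent offset otherwise.

CLEANEX buildup curves are fit as a weighted line through the origin on
the 0–25 ms mixing grid. On a saturating buildup 1 − e^(−kτ) this
estimator is biased low by curvature — exactly 18.0% for k = 20 s⁻¹ on
the default grid, as the closed form Σ τ(1−e^(−kτ))/Σ τ² shows — which
is the price of the initial-slope approximation; mixing times beyond
50 ms trigger an out-of-regime warning. Decays whose fitted rate
implies poor time-grid coverage, flat curves, and rising curves are
flagged, never silently dropped, and amides exchanging > 95% before the
first time point are routed to the CLEANEX path by the generator.

## Ensemble analysis and free-energy surfaces

Reaction coordinates are the (default mass-weighted) radius of gyration
and a side-chain distance between two chosen residues (default
heavy-atom centroid; minimum-distance, named-atom and Cα modes exist —
the centroid convention is a package choice, since source data of this
kind typically name only the residues). Free-energy surfaces bin
samples on a 40×40 grid padded 5% beyond the data range and apply
G = −k_B T ln(n/n_max), with k_B = 0.0083145 kJ/(mol·K); the occupied
minimum is exactly 0, empty bins carry an infinite sentinel and are
never interpolated. Basin analysis finds 8-neighbour local minima,
optionally after Gaussian smoothing of the occupancies (σ = 1 bin, off
by default; when on, basin free energies are read off the smoothed
surface, which suppresses single-bin Poisson noise and preserves the
ratio of equal-shape basins — smoothing is never used to fabricate
barrier heights, which are always reported from the raw surface
depth). RMSF superposes all models onto the evolving mean structure
(backbone atoms, least-squares, iterated to convergence) and reports
Cα fluctuations; a `superpose = "none"` mode exists for ensembles built
without rigid-body motion, where fitting would only redistribute a
localised displacement.

The two-state conformational generator samples the hinge torsion from a
two-Gaussian mixture, which maps to two basins in (Rg, distance). In
its reduced-coordinate mode the wells are emitted as exact equal-width
2D Gaussians, so the basin ΔG converges to −k_B T ln(p₂/p₁) with
O(n^(−1/2)) error; in the full conformational mode the
torsion-to-coordinate mapping compresses the two wells differently, and
the basin ΔG legitimately contains that well-entropy contribution in
addition to the population term. Tests of the closed form use the
reduced mode at n = 10⁵; conformational-mode tests check bimodality and
basin placement.

## Problem sizes and numerical tolerances

Default test and reproduction runs use: 50-residue synthetic proteins
for relaxation recovery; 12–20-residue toy chains with ~20–40 couplings
for tensor and refinement work; 15 Monte-Carlo refinements of 9 cycles
× 6000 steps for the replica-averaging comparison; n = 10⁵ samples for
FES closed forms. These sizes are chosen so each experiment's
statistical error sits comfortably below the property it demonstrates.
Key tolerances: exact inverse problems (noiseless SVD, noiseless
model-free) recover truth to 10⁻⁹–10⁻⁶; analytic gradients match
central finite differences to better than 10⁻⁵ relative; stochastic
recoveries (3–5% noise) are scored against their generator truth with
tolerances derived from replicate spread.

## Known limitations

Single-field relaxation data fundamentally under-determine the
model-free parameters; τ_e in particular is weakly constrained and its
recovery tolerance is wide. The sampler is a toy: it preserves the
logic of restrained annealing (energy function, replica averaging,
temperature cycles, ramped force constant) but none of the physics of
explicit-solvent MD, so refined toy ensembles say nothing about real
force-field accuracy. The steric alignment model omits electrostatics
and is approximate even as a shape model. Intrinsic-rate constants are
a fixed vendored parameterisation; variant tables exist in the
literature and shift absolute logP values. PDB I/O supports the
standard single-character chain, no insertion codes, and 1-based
residue numbering.
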