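# nmrdyn

Multi-timescale analysis of protein backbone dynamics from solution NMR.

Small globular enzymes are not static: their backbones fluctuate on
timescales from nanoseconds (bond librations, local flexibility) through
microseconds (concerted loop and domain motions) to milliseconds and
beyond (transient opening events that expose amides to solvent). Each
window is probed by a different NMR observable, and each observable needs
its own inference machinery. `nmrdyn` implements that machinery as one
coherent, tested R pipeline, aimed at comparative studies of backbone
dynamics — for example mesophilic versus hyperthermophilic homologues of
the same enzyme measured at their respective physiological temperatures.

Because raw relaxation, coupling and exchange data sets of this kind are
rarely deposited, the package pairs every analysis stage with a seeded
synthetic-data generator that produces inputs with the statistical
structure the stage assumes, together with the generating truth. Every
stage is therefore verifiable by parameter recovery, end to end.

## What it computes

**Nanoseconds — ¹⁵N relaxation and model-free order parameters.**
Single-exponential fits of R₁/R₂ intensity decays, heteronuclear NOE
ratios, R₂/R₁ flagging of slow-exchange residues (trimmed-mean + k·SD),
isotropic tumbling-time estimation, and Lipari–Szabo model-free fitting
with the two-Lorentzian spectral density

    J(ω) = (2/5) [ S²τ_m / (1 + (ωτ_m)²) + (1 − S²)τ / (1 + (ωτ)²) ],
    1/τ = 1/τ_m + 1/τ_e,

inserted into the standard dipolar + CSA expressions for R₁, R₂ and NOE
at a single field (default 700 MHz, r(N–H) = 1.02 Å, Δσ = −160 ppm).
Per-residue model selection among {S²}, {S², τ_e}, {S², R_ex},
{S², τ_e, R_ex} is by AIC.

**Microseconds — residual dipolar couplings and ensemble refinement.**
Back-calculation D = D_max · vᵀS v from bond vectors and the Saupe
alignment tensor; weighted SVD fitting of the five tensor components; Q
factors (rms(D_calc − D_exp)/rms(D_exp)); a shape-based (gyration-tensor)
steric alignment prediction; and the replica-averaged restraint
pseudoenergy

    E_total = E_ff + E_rdc,   E_rdc = α Σᵢ (⟨D_calc,i⟩_M − D_exp,i)²,

with analytic coordinate gradients (tensor frozen between refits). A
Metropolis Monte-Carlo simulated-annealing sampler (Gaussian atom moves
plus φ/ψ torsion pivots, temperature cycles, force-constant ramp) refines
M simultaneous replicas of a toy-potential chain against such restraints
and extracts the post-burn-in ensemble.

**Milliseconds — hydrogen/deuterium exchange.** The two-state scheme
closed ⇌ open → exchanged gives k_obs = k_op·k_int/(k_cl + k_int); in the
EX2 limit (k_cl ≫ k_int) the protection factor P = k_int/k_obs reports
the local opening equilibrium. The package fits HSQC decay curves,
extracts fast rates from CLEANEX initial slopes (0–25 ms mixing grid),
computes sequence-based intrinsic rates from bundled poly-DL-alanine
reference constants with nearest-neighbour corrections, and reports logP.

**Ensemble analysis.** Radius of gyration, catalytic side-chain
distances, per-residue RMSF after iterative superposition, and 2D free
energy surfaces G = −k_B T ln(n/n_max) over (global, local) reaction
coordinates with basin detection and ΔG reporting.

## Worked example

Generate relaxation data for a 50-residue synthetic protein with known
order parameters, fit it, and compare:

```r
library(nmrdyn)
set.seed(1)
truth <- data.frame(residue = 1:50,
                    S2 = pmin(0.95, pmax(0.6, rnorm(50, 0.84, 0.05))),
                    tau_e = runif(50, 20, 100))
sy <- synth_relaxation(truth, tau_m_ns = 5, noise = 0.03, seed = 11)
fit <- modelfree_fit(sy$records, tau_m = 5)
round(c(true_mean_S2 = mean(truth$S2), fitted_mean_S2 = mean(fit$S2)), 3)
#>   true_mean_S2 fitted_mean_S2
#>          0.845          0.849
```

The fitted mean S² recovers the generating mean to a few parts in a
thousand at 3% noise; per-residue models and τ_e estimates are in
`fit$model` and `fit$tau_e`. The same pattern — generate with known
truth, analyse, score the recovery — runs for RDC tensors
(`synth_rdc` → `svd_fit_tensor`), two-state ensembles
(`synth_two_state_ensemble` → `compute_fes` → `basin_analysis`),
replica-averaged refinement (`two_state_rdc_benchmark`) and hydrogen
exchange (`synth_hx` → `fit_hx_decay` → `protection_factors`).

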