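# hydropattern

Molecular-scale hydrophobicity of chemically patterned surfaces, measured the
way simulators measure it: not by contact angles, but by the free energy of
emptying water out of an interfacial probe volume and by the free energy of
binding a hydrophobic solute. The package targets self-assembled monolayers
(SAMs) of alkanethiols whose terminal groups mix a nonpolar background
(methyl) with polar or charged "pins" (hydroxyl, ammonium, guanidinium)
arranged on an SX sublattice — X methyl strands between hydrophilic strands,
each lattice step adding ~0.5 nm of spacing. It is written for computational
chemists and biophysicists who want the analysis layer of such a study —
biased-ensemble estimators, PMF reconstruction, and interfacial water
structure — as tested, reusable R functions that run on synthetic ensembles
with known ground truth.

## What it computes

**Dewetting free energy by sparse sampling.** Water density fluctuations in
a probe volume v are biased with the Hamiltonian H = H₀ + ϕÑᵥ, where
Ñᵥ = Σᵢ h̃(rᵢ) is a coarse-grained water count: each water contributes a
smoothed union-of-spheres indicator h̃ ∈ [0, 1] (Gaussian kernel σ = 0.01 nm
truncated at r_c = 0.02 nm, spheres of radius R_v = 0.6 nm), so the count is
differentiable and exerts well-defined forces −ϕ∂Ñᵥ/∂rᵢ. From the mean and
variance of Ñᵥ at a ladder of bias strengths, the unbiased free energy at
each visited mean is assembled as

F(Ñᵥ) = −(1/β) ln P᷉ᵥᵠ(Ñᵥ) − ϕ⟨Ñᵥ⟩ + ∫₀^ϕ ⟨Ñᵥ⟩ dϕ′

with the biased distribution evaluated at its mean under a Gaussian
approximation and the integral done by trapezoid on the sampled ϕ grid. The
dewetting free energy is F at the reference bias βϕ = 7 — the cost of
removing all but the most strongly bound waters — in units of kT.

**Binding free energy by WHAM.** Harmonic umbrella windows along the
surface-separation coordinate z are combined by the weighted histogram
analysis method into a potential of mean force W(z), with bootstrap errors,
a detected bulk plateau shifted to zero, a bound region defined by the 1-kT
level set around the PMF minimum (0.592 kcal/mol at 298.15 K), and

ΔG_bind = −RT ln [ ∫_bound e^(−W/RT) dz / ∫_unbound e^(−W/RT) dz ].

**Interfacial water structure.** Geometric hydrogen bonds (donor–acceptor
≤ 0.35 nm, D–H–A angle ≥ 150°), block-averaged SEMs, radial distribution
functions, water orientation distributions per hydration shell, local
hydrogen-bond densities, 2D interfacial density maps, and dewetted areas
(cells below 5 molecules/nm³). Plus a geometry builder for idealized
patterned SAM slabs (GRO/PDB output) and synthetic-ensemble generators so
every estimator can be exercised against exact ground truth.

## Worked example

Reconstruct the PMF of the packaged double-well benchmark (wells of −3 and
−1 kcal/mol, a 2 kcal/mol barrier, a flat bulk plateau) from synthetic
umbrella windows, and compute the binding free energy:

```r
library(hydropattern)

pot <- double_well_potential()
win <- generate_umbrella_windows(pot, centers = seq(0.8, 3.2, by = 0.1),
                                 k = kj_to_kcal(3000), n_per_window = 4000,
                                 seed = 7)
pmf <- wham(win)
pmf
#> <pmf_profile> 410 bins, z in [0.7377, 3.29] nm, RT = 0.5925 kcal/mol
#>   plateau: [2.242, 3.29] nm; converged in 1 iterations
bound <- identify_bound_region(pmf)
binding_free_energy(pmf, bound)
#> <binding_result> dG = -1.638 kcal/mol, bound [0.9249, 1.075] nm, unbound [2.242, 3.29] nm
```

The plateau is the detected flat bulk region (shifted to W = 0); the bound
range is the 1-kT window around the deep well near z = 1 nm; ΔG ≈ −1.64
kcal/mol is the Boltzmann-weighted depth of that well relative to a bulk
reference of the same construction — within sampling error of the exact
integral of the generating curve (−1.67 kcal/mol for these detected ranges).

The dewetting side runs the same way:

```r
model  <- number_fluctuation_model(mean_N0 = 100, var_N = 25)
series <- generate_biased_series(model, beta_phi = seq(0, 2.8, 0.2),
                                 n = 50000, seed = 1)
prof   <- sparse_sampling_free_energy(series)
autoplot(prof)      # F(⟨Ñv⟩) in kT, parabolic for a Gaussian model
```

`tidy()` and `glance()` return the tables and one-row summaries of every
result object; `autoplot()` draws them.

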