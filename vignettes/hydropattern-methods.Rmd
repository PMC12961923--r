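---
title: "Measuring surface hydrophobicity from biased water ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring surface hydrophobicity from biased water ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydropattern)
```

## The problem

Chemically patterned surfaces — here idealized self-assembled monolayers
(SAMs) of alkanethiols presenting a methyl background dotted with hydroxyl,
ammonium or guanidinium head groups on an SX sublattice — are neither
uniformly wetting nor uniformly repelling. Their effective hydrophobicity is
an emergent property of how interfacial water responds to perturbation, and
two thermodynamic probes capture it: the free energy required to empty water
out of an interfacial probe volume (cavity formation), and the free energy
of binding a hydrophobic solute brought down onto the surface. This package
implements both estimators, the interfacial water structure analytics that
accompany them, a geometry builder for the patterned slabs, and synthetic
ensemble generators that make every estimator testable against exact ground
truth without running molecular dynamics.

## Coarse-grained water counts and the linear bias

Biasing the *integer* number of waters in a volume produces impulsive
forces, so the probe volume — a union of spheres of radius $R_v = 0.6$ nm
placed over the hydrophilic groups — counts waters through a smoothed
indicator. Each sphere's sharp indicator is convolved with a truncated,
shifted, renormalized Gaussian kernel (width $\sigma = 0.01$ nm, support
$r_c = 0.02$ nm). For a water at distance $d$ from a sphere center the
angular part of the 3D convolution integrates analytically, leaving
erf/exp antiderivatives in the kernel radius; the package evaluates this
closed form, and the test suite checks it against direct numerical
quadrature of the convolution. The union over spheres is assembled as
$\tilde h = 1 - \prod_k (1 - \tilde h_k)$, which is exact wherever kernel
shells do not overlap, smooth everywhere, and avoids inclusion–exclusion
over many spheres; the coarse-grained count is
$\tilde N_v = \sum_i \tilde h(r_i) \in [0, n]$. With the bias Hamiltonian
$H = H_0 + \phi \tilde N_v$, the force on water $i$ is
$-\phi\, \partial \tilde N_v / \partial r_i$, also in closed form; the
suite verifies it against central differences at $10^{-5}$ relative where
the force is appreciable (near the kernel's outer edge the force itself
vanishes, and the check is absolute there). Setting $\sigma = 0$ selects
the sharp indicator — the exact count — and the smoothed count converges
to it as the kernel shrinks.

## Sparse sampling of the dewetting free energy

At each bias $\phi$ we record the mean and variance of $\tilde N_v$ and
assemble

$$F(\tilde N_v) = -\tfrac{1}{\beta}\ln P_v^{\phi}(\tilde N_v)
  - \phi \langle \tilde N_v \rangle
  + \int_0^{\phi} \langle \tilde N_v \rangle\, d\phi',$$

evaluating the biased distribution at its mean under a Gaussian
approximation, $-\tfrac{1}{\beta}\ln P = \tfrac{1}{2\beta}\ln(2\pi
\mathrm{var}\,\tilde N)$, and integrating the mean over the sampled grid by
trapezoid with no extrapolation. The profile is shifted to $F = 0$ at
$\phi = 0$, and the dewetting free energy is $F$ at the reference bias
$\beta\phi = 7$ — the cost of removing all but the most strongly bound
waters, the package's surface-hydrophilicity measure. The reference bias
must actually be sampled; interpolating to it is refused, because the
response near a dewetting transition is steep and interpolation there is
not trustworthy. The means (not final-frame counts) after the equilibration
discard define the reference state.

For a Gaussian fluctuation model with mean $N_0$ and variance $v$, the
exact tilted distribution gives a linear response with slope $-v/N_0$ in
$\beta\phi$ (the compressibility slope) and an exactly parabolic
$\beta F(N) = (N - N_0)^2 / 2v$, so the estimator's accuracy is measured
against closed forms: at 15 bias points with 50,000 samples each it
recovers the parabola to better than 0.2 kT over the visited range. The
benchmark bias grid runs $\beta\phi \in [0, 2.8]$ so the model's mean
(100 → 30) stays far from the $N \ge 0$ boundary where the Gaussian
picture would break; the mean is then linear in $\phi$ and the trapezoid
rule is exact, leaving only sampling noise. Note a property of the exact
Gaussian model worth stating explicitly: at a fixed reference bias the
dewetting free energy is $(\beta\phi_{\mathrm{ref}})^2 v / 2$, *increasing*
in the variance — a narrower (more strongly pinned) distribution sheds
fewer waters by $\beta\phi = 7$ and costs less to get there. Differences in
hydrophilicity between real surfaces come from the transition region
(modeled here by the optional two-basin variant), not from the
single-Gaussian branch.

## WHAM and the binding free energy

Umbrella windows (harmonic springs, stiffness in kcal/mol/nm² with an
explicit 4.184 conversion for kJ inputs) are combined by the weighted
histogram analysis method. Two numerical choices matter and are deliberate:

* **Bin-averaged bias factors and fine bins.** With stiff springs
  ($k = 717$ kcal/mol/nm², window width $\approx 0.03$ nm) the histogram
  discretization bias scales as the squared bin width and is visible at
  coarse binning. The solver therefore averages $e^{-\beta u_i(z)}$ over
  each bin with 5-point Gauss–Legendre quadrature and defaults to one bin
  per 1/16 of the window spacing; bins beyond the outermost windows whose
  counts fall below 1% of the maximum are dropped as unconstrained.
* **Convex solve, then self-consistency.** The Picard fixed-point
  iteration converges slowly for long window chains, so the solver first
  minimizes the equivalent convex maximum-likelihood objective with BFGS
  (whose stationary point is exactly the WHAM fixed point) and then
  polishes with Picard iterations until the largest change in any window
  free energy is below the tolerance (default $10^{-8}$ kT).
  Non-convergence and non-overlapping windows are hard errors naming the
  residual or the offending pair.

The PMF is shifted so its mean over the bulk plateau is zero. The plateau
is detected as the longest trailing stretch (≥ 0.5 nm) of the lightly
smoothed profile whose total variation stays under 0.3 kcal/mol with no
material trend; if none qualifies the trailing quarter of the range is used
with a warning, and the range can always be supplied explicitly. Bootstrap
errors resample each window with replacement and rerun WHAM on the same
bins (100 trials by convention, deterministic under the seed).

The bound region is the contiguous 1-kT level set
($W \le W_{\min} + 0.592$ kcal/mol) around the global minimum lying below
the plateau by more than a noise floor; with no such minimum the surface is
reported as non-binding rather than assigned a number. When two minima tie,
the wider interval wins and ties break toward smaller $z$, flagged in the
output. The binding free energy is the log-ratio of trapezoidal Boltzmann
integrals over the bound and unbound ranges; with the plateau at zero the
denominator is effectively the width of the reference region, so doubling
that width shifts $\Delta G$ by $RT\ln 2$ — a property the tests assert,
along with invariance under joint constant shifts. RT defaults to 298.15 K
(0.592 kcal/mol) to match the conventional 1-kT window even though
simulations of this kind typically thermostat at 300 K; the temperature is
a parameter everywhere.

## Interfacial water analytics

Hydrogen bonds use the geometric criterion: donor–acceptor distance
$\le 0.35$ nm and donor–hydrogen–acceptor angle $\ge 150^\circ$
(near-linear). The angle threshold follows the figure-caption convention
$\ge 150^\circ$; a "less than 150°" reading would accept nearly every
triple and is treated as an inversion. Candidate pairs come from a periodic
cell list, and the suite requires exact set equality between the cell-list
path, the brute-force path, and an independently coded exhaustive
all-triples oracle. Radial distribution functions use exact spherical-shell
volumes and minimum-image distances; orientation distributions histogram
$\cos\theta$ between each O–H bond vector and the oxygen-to-reference
vector (a molecular-dipole mode is provided as an alternative convention —
the choice of vector pair is genuinely ambiguous in the field and neither
is asserted as canonical), normalized so the integral over $\cos\theta$ is
one. Local hydrogen-bond densities count bonds by the shell of the donor
oxygen (0.35 nm shells). Density maps average oxygen counts in lateral
cells over a z slab (~0.6 nm, roughly two hydration layers); the dewetted
area counts cells below 5 molecules/nm³, either in total or restricted to
the largest 4-connected component — both are exposed because the
literature's convention is unstated. Block averaging uses 5 contiguous
blocks by default (a stated convention, not a fitted one).

## The synthetic-data generators

The `synth` functions emulate exactly the statistical structure the
estimators assume, nothing more: Boltzmann samples on a tabulated 1D
potential by adaptive random-walk Metropolis (step tuned to ~45%
acceptance during burn-in, recording every 10th step so recorded samples
are effectively independent — the samplers' contract is the *target
distribution*, and the estimator benchmarks assume roughly independent
draws); integer water counts drawn from the exactly computed tilted
distribution $P_0(N)e^{-\beta\phi N}$ (single-Gaussian or two-basin);
harmonic umbrella windows advanced as parallel chains; rigid 3-site water
boxes (O–H 0.09572 nm, H–O–H 104.52°) with planted hydrogen-bond pairs
realized exactly and laid out on exclusive grid slots so periodic images
cannot confound them; and 2D density grids with planted dry discs. All
generators are deterministic under their seed and record it.

What passing tests on these ensembles shows — and does not show: the
estimators are correct implementations of their definitions, recover known
ground truth at the benchmark sizes, and agree with independent oracles.
Synthetic water is uncorrelated and orientationally isotropic; real
interfacial water has structure, autocorrelation, and finite-sampling
pathologies (hysteresis at dewetting transitions, slow window
equilibration) that no desk-scale ensemble reproduces, so accuracy numbers
here bound estimator error, not simulation error.

## The SAM geometry builder

Strands are all-trans alkanethiols (10 backbone carbons by default) with
the head group appended, twisted 53° about the chain axis and tilted 30°
from the surface normal, replicated on a rectangular lattice
(0.5 nm × 0.432 nm) with hydrophilic strands every $(X+1)$ sites — in both
lateral directions by default (`sublattice2d`, isolated pins), or in
stripes. Backbone atoms are placed *on* the chain axis at the all-trans
axial rise derived from the 0.154 nm C–C bond and the tetrahedral angle
(0.1257 nm per bond); the lateral zig-zag is deliberately omitted so the
untilted strand is exactly collinear with the surface normal, which keeps
tilt/twist semantics exact and is sufficient for head-group placement —
these structures are inputs for probe-volume construction and spacing
measurements, not for force-field energetics. Patterns whose period does
not divide the lattice warn, because the periodic wrap then creates one
irregular spacing. Structures write to GRO (hand-formatted, fixed-width)
and PDB (via bio3d), and `head_spacing()` measures periodic
nearest-neighbor head distances along either lattice axis.

## Problem sizes and defaults

The packaged benchmarks are sized for a single CPU: the double-well WHAM
benchmark uses 25 windows spaced 0.1 nm with $k = 3000$ kJ/mol/nm² and
20,000 recorded samples per window; the sparse-sampling benchmark uses 15
bias points with 50,000 draws each; oracle equivalence for WHAM runs 8,000
samples per window against a sample-based multistate-reweighting estimator.
Defaults throughout are the field's conventional values: $\sigma = 0.01$
nm, $r_c = 0.02$ nm, $R_v = 0.6$ nm, d$_{max}$ = 0.35 nm, angle ≥ 150°,
low-density threshold 5 molecules/nm³, reference $\beta\phi = 7$, 100
bootstrap trials, 1-kT window 0.592 kcal/mol. The run configuration
(`load_config()`) carries every one of them, hashes semantically, and
validates before any computation.

## Known limitations

* The union indicator's product form deviates from the exact union
  integral only where the 0.02 nm kernel shells of two spheres overlap the
  same water; with $R_v = 0.6$ nm this region is geometrically thin, and
  the bounds tests cover it, but the deviation is not identically zero.
* Sparse sampling evaluates the biased distribution at its mean under a
  Gaussian approximation; strongly bimodal windows (mid-transition) violate
  it, which is why the dewetting free energy is anchored at a sampled
  reference bias rather than integrated through the transition's tails.
* WHAM assumes within-bin constancy of the unbiased density; the fine
  default binning makes the residual bias small against the benchmark's
  0.15 kcal/mol budget but it is not exactly zero.
* The plateau detector needs an actual plateau; PMFs truncated before bulk
  behavior must supply `plateau_range` explicitly.
* The geometry builder makes idealized structures (no gold substrate, no
  hydrogens on strands, no minimization); it exists to define patterns,
  head positions and probe volumes, not to start simulations unedited.
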