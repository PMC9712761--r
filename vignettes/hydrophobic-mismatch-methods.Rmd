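---
title: "Membrane elastic theory, lattice assembly and single-molecule kinetics in mismatchkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane elastic theory, lattice assembly and single-molecule kinetics in mismatchkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mismatchkit)
```

# Scope

`mismatchkit` implements a quantitative framework for studying how the
*hydrophobic mismatch* between a membrane protein and its lipid bilayer
modulates protein oligomerization, association/dissociation kinetics,
lateral diffusion, and the organization of 2D protein arrays. The model
system it is built around is the *E. coli* water channel AqpZ reconstituted
in mono-unsaturated PC bilayers of chain length C14-C20, observed by
high-speed AFM: AqpZ tetramers form p4\(2_1\)2 crystalline arrays (unit cell
95 Å, two tetramers per cell, 45.125 nm² per tetramer) that exchange
molecules with a 2D gas of freely diffusing tetramers.

Five analysis layers are provided, each with a synthetic-data generator so
the entire chain is testable without instrument data:

1. a continuum elastic solver for the leaflet deformation field around
   rigid inclusions (`solve_field_1d()`, `solve_field_2d()`,
   `pair_potential_curve()`, `local_configuration_energies()`);
2. a stochastic lattice simulator of array assembly driven by those
   energies (`run_automaton()`, `automaton_scale_sweep()`);
3. censored dwell-time kinetics of single-molecule binding events
   (`classify_events()`, `fit_exponential_mixture()`, `delta_g_diff()`,
   `delta_g_asso()`, `oligomer_energy()`, `barrier_height()`);
4. fixed-position height-spectroscopy estimators of the diffusion
   coefficient and unbound concentration (`detect_events()`,
   `analyze_height_trace()`);
5. structure-based hydrophobic thickness from atomic coordinates
   (`normalize_structure()`, `unroll_surface()`, `hydrophobic_thickness()`),
   and regression utilities extrapolating measured energies to zero
   mismatch (`fit_vs_mismatch_sq()`, `fit_diffusion_vs_mismatch()`).

# The elastic model

## Energy functional and leaflet convention

A rigid inclusion whose hydrophobic belt is thinner or thicker than the
bilayer core forces each leaflet to deviate locally by
\(u_0 = \tfrac12\,|l_\mathrm{bilayer} - l_\mathrm{protein}|\) at the
protein-lipid interface. The leaflet height deviation \(u(x,y)\) relaxes by
balancing compression against bending:

\[
G_\mathrm{def} \;=\; \tfrac12 \iint
\Big[ K_A \big(u/l\big)^2 + \kappa_b \big(\nabla^2 u\big)^2 \Big]\,
\mathrm{d}x\,\mathrm{d}y .
\]

One leaflet is solved with monolayer moduli (\(K_A/2\), \(\kappa_b/2\)) and
the energy doubled for the mirror leaflet; because the stationarity
equation depends only on the ratio \(K_A/(\kappa_b l^2)\), the solved field
is identical to a full-moduli solve.

Defaults: \(K_A = 58\,k_BT/\mathrm{nm}^2\) (≈ 0.24 N/m, typical of fluid PC
bilayers; mono-unsaturated PCs of different tail length have very similar
stretch moduli) and \(\kappa_b = 20\,k_BT\), identical across C14-C20 — the
apparent proportionality of \(\kappa_b\) to thickness is weak and C14/C20
behave symmetrically in the data this package models. Both are arguments of
`bilayer_spec()` and can be overridden. The bilayer hydrophobic thickness
follows the linear model `bilayer_thickness()`: 24 Å at C14 to 34 Å at C20
(~1.7 Å per carbon), and the default protein thickness is the AqpZ
membrane-exposed value of 28.6 Å, so C14 and C20 carry mismatches
\(u_0\) = 2.3 and 2.7 Å while C16 and C18 are nearly matched (0.63, 1.03 Å).

The decay length \(\lambda = (\kappa_b l^2/K_A)^{1/4}\) is ≈ 1.2-1.4 nm for
these defaults and controls every numerical scale below.

## Discretization

The solver minimizes the discretized energy on a regular square grid
(default spacing \(\lambda/4\); the bending term squares a 5-point
Laplacian into the 13-point biharmonic form). Boundary conditions:

* **Dirichlet** \(u = u_0\) on the protein-lipid interface. Stencil arms
  crossing the interface are shortened to the true crossing point
  (Shortley-Weller cut-boundary treatment), and compression weights of cut
  cells use the supersampled lipid area fraction, so the curved boundary is
  honored to sub-grid accuracy. Lipid nodes within \(0.1h\) of the boundary
  are absorbed into the Dirichlet set to keep the cut arms well
  conditioned.
* **Free contact slope**: minimizing the energy with only the value
  constrained leaves the contact slope free — the natural boundary
  condition of the functional — so no explicit condition is imposed.
* **Clamped far field**, \(u = 0\) on the outer two node rings, placed at
  least \(10\lambda\) from any inclusion (the field has decayed below 1% of
  \(u_0\) well before that).

The resulting system is sparse, symmetric positive definite and solved by
Cholesky factorization (`Matrix`). Energy is integrated only over lipid
nodes — the area occupied by protein carries no deformation energy.
Because the problem is linear, solved fields scale exactly linearly in
\(u_0\) and energies exactly quadratically; the test suite exploits this.

In one dimension the same functional has the closed-form minimizer
\(u(x) = u_0 e^{-\beta x}\cos\beta x\) with
\(\beta = (K_A/(4\kappa_b l^2))^{1/4}\) (the free-slope condition
\(u''(0)=0\) selects the pure-cosine branch) and two-leaflet line energy
\(\kappa_b \beta^3 u_0^2\). `field_1d_closed_form()` exposes this oracle;
the numerical 1D solver agrees with it to 0.1% and the 2D solver reproduces
the profile across a straight boundary slice.

Convergence: halving the grid from \(\lambda/8\) to \(\lambda/16\) changes
a single-inclusion energy by ~1.4%. Ratios of configuration energies
(\(\psi_\mathrm{norm}\), pair-potential differences) converge much faster
because the boundary discretization error is common mode; they are stable
to better than 1% from \(\lambda/4\) on.

## Pair potential

`pair_potential_curve()` places two identical inclusions at edge-to-edge
distance \(d\) and reports
\(\Delta G_\mathrm{elas}(d) = G_\mathrm{def}(d) - G_\mathrm{def}(d_\mathrm{ref})\)
with \(d_\mathrm{ref} = 20\) nm, far beyond the interaction range.
With the default moduli the curve is **attractive at contact** (shared
deformation field), passes through a **repulsive maximum** near
\(d \approx 2\text{-}3\) nm (the saddle-shaped bridging field costs bending
energy), stays positive into the 3.5-7 nm band and is negligible beyond
8 nm. The positions of the band edges scale with \(\lambda\): reports that
place the repulsive shoulder out to ~7 nm and the attraction onset at
~3.5 nm correspond to a larger decay length than the physically measured
moduli of these lipids produce; with the defaults here the same sign
structure appears compressed toward shorter distances. The package asserts
the structure (attraction at short range, repulsive shoulder reaching the
3.5-7 nm band, decay beyond 8 nm), not specific band edges.

## Local-configuration energies and contact packing

Array assembly is coarse-grained onto a square lattice with spacing
\(a = 6.7\) nm (the nearest-neighbor tetramer distance of the p4\(2_1\)2
array, \(9.5/\sqrt2\) nm). A 2×2 window of lattice sites has five
configurations — empty or 1-4 occupied sites — and
`local_configuration_energies()` assigns each its continuum deformation
energy \(\psi_1\ldots\psi_4\) by solving the 2D field of the corresponding
protein cluster.

**Geometry.** A free-standing AqpZ tetramer is modeled either as a
cylinder of footprint area 45.125 nm² (radius 3.79 nm) or as a four-lobed
"clover leaf". On the lattice, however, neighboring proteins are *in
contact*: rigid bodies cannot interpenetrate, and a disc of footprint
radius 3.79 nm would overlap its neighbor at \(a = 6.7\) nm. Lattice
configurations therefore use **contact packing**, fully determined by the
lattice constant: a cylinder of radius \(a/2\), or a clover leaf with leaf
radius and center offset \(a/4\) whose four protomer lobes point at the
four bonded neighbors (the contact topology of the array, where each
tetramer touches four neighbors through its protomers). With \(u_0=2.3\) Å
and the default moduli this yields

```{r psi, eval = FALSE}
local_configuration_energies("cylinder")$psi_norm     # 1.00 1.78 2.61 3.05
local_configuration_energies("clover_leaf")$psi_norm  # 1.00 1.88 2.83 3.53
```

with the strict ordering \(\psi_1<\psi_2<\psi_3<\psi_4\). These
normalizations agree with published continuum values for the two shape
models ({1.00 1.81 3.01 3.50} cylindrical, {1.00 2.06 3.22 4.10}
clover-leaf) to within 15% per component; the residual deviation reflects
cross-section details (lobe shape, contact area, moduli) that are not
identifiable from the published normalizations alone. Because energies are
exactly quadratic in \(u_0\), \(\psi_\mathrm{norm}\) is independent of the
mismatch and the overall scale \(\psi_1\) acts as the single
mismatch-squared parameter downstream.

The energy change of a lattice rearrangement is
\(\Delta\psi = \sum_i \delta n_i\,\psi_i\) over the window-count changes
\(\delta n_i\) (`delta_psi()`, `delta_psi_from_counts()`). The canonical
moves — a diffusing molecule binding flat onto an array edge
(\(\delta n = \{-2,-2,2,0\}\), counting the four windows the molecule
leaves behind at its isolated position) and one filling an inner corner
(\(\delta n = \{-4,0,0,1\}\)) — evaluate to +0.40/−0.50 (cylindrical
normalization) and +0.32/+0.10 (clover-leaf), so corner filling is always
favored over edge protrusion and arrays grow with straight, compact
borders.

# The assembly automaton

`run_automaton()` evolves an occupancy lattice by asynchronous single-site
dynamics exchanging molecules with a reservoir of diffusers at 2D
concentration \(C_U\). A site is eligible for insertion or removal when its
occupied-neighbor count is 1-3 (the same rule in both directions; interior
4-bond molecules are immobile). Rates follow first-order barrier kinetics
with the transition state at the unbound-diffuser level:

* association attempts succeed with probability \(\propto e^{\mu}\),
  \(\mu = \ln(C_U a^2)\) — arrival is limited by the diffuser
  concentration, not by the depth of the final state;
* a bound molecule unbinds with probability \(\propto e^{\Delta}\), where
  \(\Delta = E_{PP} n_b + \Delta\psi_\mathrm{re} < 0\) is its binding
  energy relative to the unbound diffuser: \(E_{PP}\) per direct
  protein-protein bond plus the membrane rearrangement energy
  \(\Delta\psi_\mathrm{re} = \Delta\psi_\mathrm{window} - 4\psi_1\)
  (an isolated diffuser carries \(4\psi_1\) of deformation in the window
  bookkeeping, which it sheds on binding).

Both exponents are jointly shifted when either would exceed one, so the
chain satisfies **exact detailed balance** with respect to
\(H = E_{PP} B + \sum_i n_i\psi_i - (\mu + 4\psi_1) N\); on enumerable toy
lattices the empirical stationary distribution matches the Boltzmann
distribution of this Hamiltonian (χ² test in the suite). Unlike plain
Metropolis acceptance — which would make every dissociation downhill and
saturate at probability one — the barrier form keeps the dwell-time ratio
of one-bond and two-bond states equal to their binding-energy difference,
which is exactly the observable the experiments read out
(\(\Delta G_\mathrm{diff} = -\ln(\tau_2/\tau_1)\)).

Time is measured in sweeps (one proposal per site on average); the mapping
to seconds is a calibration left outside the model. Runs are
bit-reproducible under a seed (the R RNG is used). The event log records
every accepted flip; complete association→dissociation episodes of a site
are extracted with the same rules as the experimental classifier —
bond class fixed at association, episodes whose neighborhood changed
mid-event discarded.

`automaton_scale_sweep()` measures \(\Delta G_\mathrm{asso} =
-\ln(C_B/C_U)\) (time-averaged bound density over the lattice against the
reservoir concentration) and \(\Delta G_\mathrm{diff}\) across a sweep of
the deformation scale \(\psi_1\), the proxy for squared mismatch. Its
default conditions — \(E_{PP} = -2.8\,k_BT\), \(C_U = 100\,\mu m^{-2}\),
64×64 sites, a frozen 12×12 nucleus, 500 burn-in + 20,000 measured sweeps —
put the system near array/reservoir coexistence (the per-site growth free
energy \(2E_{PP} + \Delta\psi_{re2} - \mu\) changes sign inside the swept
range), the regime the experiments are in: arrays neither dissolve nor fill
the lattice, so bound density and dwell times respond to the mismatch
scale. In that regime \(\Delta G_\mathrm{asso}\) increases and
\(\Delta G_\mathrm{diff}\) decreases monotonically with the scale, and
cluster morphology sharpens from ragged aggregates at zero scale to
compact rectangles at large scale (bonds per molecule in the suite's
compactness check). These are trend-level reproductions: the published
automaton's exact update table is not available, so the rules above are
this package's own construction with the same equilibrium and the same
qualitative kinetics, not a line-by-line replication.

# Dwell-time kinetics

`classify_events()` turns a registered occupancy movie into complete
one-bond/two-bond events (class = occupied 4-neighbors at association;
class-changing, boundary-touching, zero-bond and ≥3-bond episodes are
dropped — three-bond events are rare and not analyzed). Dwell times are
multiples of the frame interval with a one-frame minimum, so
`fit_exponential_mixture()` maximizes the *interval-censored* likelihood
of the two-exponential survival model

\[
P(B)(t) = c_1 e^{-t/\tau_1} + (1-c_1)\,e^{-t/\tau_2},
\qquad \Pr(k\ \text{frames}) = S((k{-}1)\Delta t) - S(k\Delta t),
\]

rather than least squares on the empirical curve: with \(\tau_1\)
comparable to the frame interval (0.5-0.9 s against 1 s frames) the
discretization bias of a naive fit is first order, while the censored MLE
recovers \(\tau_2\) from frame-discretized and continuous data within 2%
at large n. Standard errors come from the observed information; a
likelihood-ratio comparison against a single-exponential fit flags
non-identifiable mixtures. The constrained variant (`fix_tau1 = 0.7`)
mirrors the stabilization used when the fast constant is below the frame
rate. Parameter recovery at the realistic sample sizes (288-1096 events)
is unbiased within Monte-Carlo error; at n = 1096 the slow constant is
recovered within one standard error (median over replicates).

Equilibrium and kinetic energies (all in \(k_BT\)):
\(\Delta G^0_\mathrm{asso} = -\ln(C_B/C_U)\) with
\(C_B = 22{,}161\,\mu m^{-2}\) from the unit cell
(`bound_concentration(95, 2)`); \(\Delta G^0_\mathrm{diff} =
-\ln(\tau_2/\tau_1)\); oligomer-state differences
\(-\ln(N_{s2}/N_{s1})\) from occurrence counts with Poisson errors; and
the Arrhenius barrier \(\ln(A\tau)\) with \(A \sim 10^9\text{-}10^{10}\,
s^{-1}\), which places a 10 s dwell behind a ~23-25 \(k_BT\) barrier.
Note that evaluating \(\Delta G^0_\mathrm{asso}\) literally from the
bundled \(C_U\) table gives ≈ −3.3 \(k_BT\) for C18, whereas the bundled
reference energy table lists −6.6: the normalization linking the two in
the original analysis is not stated, so `delta_g_asso()` returns the
literal value and the regression layer consumes the reference energies as
given.

# Height spectroscopy

`detect_events()` thresholds a fixed-position height-time trace at
\(H_T = \text{mean} + 5\sigma\) of the baseline distribution, with the
baseline re-estimated iteratively on sub-threshold samples (initialized
robustly from median/MAD so that frequent tall events cannot inflate the
first estimate) and super-threshold runs merged across sub-2-sample gaps.
Estimators: \(w = 2(\sqrt{A/\pi} + r_\mathrm{tip})\) for the detection
width (9.58 nm for the tetramer footprint and a 1 nm tip),
\(D_U = w^2/(4\tau_D)\) from the characteristic event dwell, and
\(C_U = (t_{z>H_T}/t_\mathrm{total})/A_\mathrm{protein}\) from the
occupancy fraction. \(\tau_D\) is by default the fitted decay constant of
the dwell-distribution tail (robust to truncation of sub-sample events);
the plain mean is also available (`event_dwell_time()`).

The generator `gen_height_trace()` simulates point particles diffusing by
2D Brownian motion in a periodic box, detected while their footprint disc
covers the tip position, with per-event heights uniform in 1.0-1.5 nm and
Gaussian baseline noise (σ = 0.1 nm). Under this measurement model the
concentration estimator is accurate (the detection disc area equals the
protein footprint, and recovery is within ~10-30% across the realistic
range), and false positives on pure noise follow the 5σ Gaussian tail
bound (≪ 1 event per 10⁶ samples).

**A deliberate caveat**: for a memoryless threshold detector the dwell
distribution of disc excursions has an exponential tail of
\((w/2)^2/(j_{01}^2 D)\) (slowest mode of the absorbing disc,
\(j_{01} \approx 2.405\)) — about 5.8× shorter than the crossing-time
scale \(w^2/(4D)\) that the estimator inverts. Real height-spectroscopy
dwell times are additionally shaped by the instrument's feedback response,
which merges re-entries over microseconds and lengthens apparent dwells
toward the crossing-time scale; instrument modeling is outside this
package's scope. Consequently \(D_U\) recovered from the *synthetic*
traces is biased high by a factor of ~4 even though the estimator applied
to experimentally calibrated dwell times reproduces the published
coefficients exactly (e.g. \(\tau_D = 39\,\mu s\), \(w = 9.58\) nm →
0.59 µm²/s). The test suite asserts the parts of the closure that the
measurement model supports (concentration, false-positive control,
threshold monotonicity, bounded rate dependence) and documents this bias
rather than hiding it behind a fitted correction factor. For the same
reason the recovered D retains a mild (≈ ±25%) dependence on sampling rate
through the sample-based gap merging.

# Structure-based hydrophobic thickness

`normalize_structure()` centers the heavy-atom cloud and aligns the
symmetry axis with z (from the coordinate covariance: a rotationally
symmetric protein has two nearly equal principal variances, and the
distinct eigenvector is the axis; the degeneracy test is floored at the
eigenvalue sampling noise \(\sqrt{2/n}\), and an explicit axis hint
overrides it). `unroll_surface()` maps the surface to a (θ, z) pixel grid
(2° × 1 Å) and scores each pixel for hydrophobic/hydrophilic/aromatic
surface exposure with the Gaussian-weighted sum over the atoms in a
10 Å × 10° region,

\[
R_p = \sum_i \delta_{iR}\,
e^{-(z_i-z_p)^2/\sigma_z^2}\,
e^{-(r_i-r_\mathrm{max})^2/\sigma_r^2}\,
e^{-(\theta_i-\theta_p)^2/\sigma_\theta^2},
\]

where \(r_\mathrm{max}\) is the most exposed radius in the region — buried
residues are suppressed. Defaults \(\sigma_z = 3\) Å, \(\sigma_r = 2\) Å,
\(\sigma_\theta = 5°\); residue classes: hydrophobic {ALA VAL LEU ILE MET
PHE PRO GLY CYS}, aromatic {TRP TYR}, hydrophilic otherwise — all
arguments, since neither the σ values nor the class table are uniquely
standard, which is also why thickness values carry a ±1.5 Å tolerance
band rather than being exact targets. The pixel class is the score argmax;
`hydrophobic_thickness()` measures, per angular column, the longest
z-contiguous hydrophobic run (aromatic pixels are excluded from the band:
only hydrophobicity vs hydrophilicity defines the thickness) and reports
\(l = A_\mathrm{hydrophobic}/c_\mathrm{surface}\), the mean band height.
Restricting `theta_range` to the sector a protomer exposes to its neighbor
yields the protomer-interface thickness instead of the membrane-exposed
one — the quantity that rationalizes why thick C20 bilayers destabilize
the tetramer (the interface band, ~33 Å in AqpZ, matches C20 while the
membrane-exposed band, ~28.6 Å, matches a hypothetical C17 bilayer).

On synthetic cylinders with known belts the measurement is accurate to one
pixel row, invariant under rotation, and stable to pixel-size halving
within 5%; aromatic girdle rings added outside the belt do not move the
band edge by more than a row.

# Mismatch regressions

`mismatch_series()` attaches \(u_0\) and \(u_0^2\) (linear thickness model
+ protein thickness) to any per-bilayer measurement.
`fit_vs_mismatch_sq()` regresses energies on \(u_0^2\) — the elastic
deformation energy is quadratic in mismatch, so the intercept estimates
the membrane-independent direct protein-protein energy — and
`fit_diffusion_vs_mismatch()` regresses \(D_U\) on \(u_0\) (effective
membrane viscosity scales linearly with mismatch). Unweighted OLS is the
default (the published fits do not state weighting); a 1/se² weighted
variant is available. On the bundled reference tables these reproduce the
published intercepts: \(\Delta G^0_{P\!-\!P(\mathrm{diff})} = -2.3\,k_BT\),
\(\Delta G^0_{P\!-\!P(\mathrm{asso})} = -6.9\,k_BT\), and a zero-mismatch
diffusion coefficient of 0.7 µm²/s; their ratio, ~3, is the average
number of bonds an array-bound molecule engages.

# Synthetic data: what it does and does not emulate

* `gen_dwell_times()` draws from the two-exponential mixture and applies
  exactly the frame discretization the fitter inverts. It does not emulate
  particle-picking errors or missed short events beyond the one-frame
  floor.
* `gen_occupancy_movie()` scripts bound-state events of known class and
  dwell next to a static array; it does not emulate drift, registration
  error, or molecules diffusing through the field of view.
* `gen_height_trace()` is a true 2D Brownian measurement model with binary
  disc detection; it omits the instrument response (see the caveat above),
  tip-shape convolution and multi-species mixtures.
* `gen_toy_structure()` builds cylindrical pseudo-proteins with exact
  belts (ring offsets chosen so class boundaries fall between rings);
  it is a synthetic stand-in, not a protein model.

Passing tests on these generators therefore demonstrate the correctness of
the estimators under their stated measurement models, not robustness to
every artifact of real HS-AFM data.

# Problem sizes and tolerances in the shipped tests

The suite runs at deliberately desk-sized settings: elastic solves on
grids of \(\lambda/4\)-\(\lambda/8\) (up to \(\lambda/16\) once, for the
convergence check), \(\psi_\mathrm{norm}\) at \(\lambda/5\); automaton
equilibrium checks at 4×10⁵ sweeps on 3×3 lattices and trend sweeps of
20,000 sweeps on 64×64; mixture-recovery studies of 60-200 replicates at
the realistic event counts; height-trace batches of 0.2-0.5 s at 0.2-2
Msamples/s. These sizes keep every check inside a normal development cycle
while leaving all conclusions statistically resolved (trend checks use
≥100 events per class; recovery checks compare medians against
replicate-level standard errors).

# Known limitations

* Curvature, tension, tilt degrees of freedom, spontaneous curvature and
  thermal (Casimir-like) forces are outside the elastic model; many-body
  effects enter only through the four 2×2 local configurations.
* The automaton has a single species, no explicit diffusers, no rotational
  states and an update rule constructed here (equilibrium-exact, trend
  faithful, but not a published rule table).
* The absolute time unit of the automaton (sweeps) and of the
  height-spectroscopy dwell bias are calibrations that require instrument
  information not modeled here.
* Structure scoring uses heavy atoms only and a configurable but
  non-canonical residue classification; thickness values should be treated
  as ±1-2 Å.
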