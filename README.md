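# mismatchkit

Quantitative analysis of **membrane-mediated protein interactions driven by
hydrophobic mismatch**. The package is built around a well-defined model
system — the tetrameric water channel AqpZ diffusing, oligomerizing and
assembling into p4&#x2082;&#x2081;2 crystalline arrays in fluid PC bilayers
of chain length C14–C20 — but every layer is parameterized and reusable for
other inclusion/bilayer systems.

When a membrane protein's hydrophobic belt (thickness
*l*<sub>protein</sub>) does not match the bilayer core
(*l*<sub>bilayer</sub>), each leaflet deforms by
*u*<sub>0</sub> = ½|*l*<sub>bilayer</sub> − *l*<sub>protein</sub>| at the
protein–lipid interface. The leaflet height field *u*(x, y) relaxes by
balancing compression against bending,

&nbsp;&nbsp;&nbsp;&nbsp;*G*<sub>def</sub> = ½ ∬ [ *K*<sub>A</sub> (*u*/*l*)² + *κ*<sub>b</sub> (∇²*u*)² ] dx dy,

and the resulting deformation energy is what couples proteins through the
membrane: it produces a distance-dependent pair potential (attraction at
contact, a repulsive shoulder at intermediate separations), biases the
kinetics of association and dissociation at array edges, slows diffusion,
and sets the relative energies ψ₁…ψ₄ of lattice "local configurations"
that govern 2D array morphology.

The package provides, as tested, composable layers:

* **Elastics** — sparse finite-difference solver for the deformation field
  around rigid inclusions (cylinder or clover-leaf cross-sections) with
  cut-boundary treatment of the curved interface; deformation energies,
  pair potentials (`pair_potential_curve()`), and local-configuration
  energies (`local_configuration_energies()`), validated against a 1D
  closed form.
* **Assembly automaton** — grand-canonical lattice simulator of array
  growth/shrinkage whose moves are weighted by direct bond energies plus
  Δψ (`run_automaton()`, `automaton_scale_sweep()`); exactly in detailed
  balance, with single-molecule event logs.
* **Kinetics** — single-molecule event classification from occupancy
  movies and interval-censored maximum-likelihood fitting of
  two-exponential dwell-time mixtures (`fit_exponential_mixture()`), with
  the derived energies ΔG⁰<sub>asso</sub> = −ln(C<sub>B</sub>/C<sub>U</sub>),
  ΔG⁰<sub>diff</sub> = −ln(τ₂/τ₁), oligomer-state energies from occurrence
  counts, and Arrhenius barriers ln(Aτ).
* **Height spectroscopy** — event detection at mean + 5σ in fixed-position
  height–time traces, diffusion coefficient D<sub>U</sub> = w²/(4τ<sub>D</sub>)
  and unbound concentration C<sub>U</sub> from the occupancy fraction
  (`analyze_height_trace()`).
* **Structure** — hydrophobic thickness from atomic coordinates via
  unrolled-surface hydropathy scoring (`unroll_surface()`,
  `hydrophobic_thickness()`), for the membrane-exposed surface or a
  protomer-interface sector.
* **Energetics** — regressions of measured energies on u₀² and of
  diffusion on u₀, extrapolating to the zero-mismatch (membrane-independent)
  protein–protein energies (`fit_vs_mismatch_sq()`).
* **Synthetic data** — generators for every input (dwell mixtures,
  Brownian height traces, scripted occupancy movies, toy PDB structures),
  so the full chain runs and is tested without instrument data.

See the methods vignette (`vignettes/hydrophobic-mismatch-methods.Rmd`)
for the models, assumptions, numerical choices and known limitations.

## Worked example

Fit a night's worth of single-molecule bound-state dwell times (here
synthetic, drawn at the C18 ensemble parameters) and convert them to a
bond-strengthening energy:

```r
library(mismatchkit)

set.seed(1)
d <- gen_dwell_times(c1 = 0.55, tau1 = 0.77, tau2 = 8.2, n = 1096, dt = 1)
fit <- fit_exponential_mixture(d, dt = 1)
fit
#> mixture_fit (n = 1096): c1 = 0.62, tau1 = 0.82 s, tau2 = 9.31 s, logL = -2339.0

delta_g_diff(fit$tau1, fit$tau2, fit$se[["tau1"]], fit$se[["tau2"]])
#> energy_estimate (diff): -2.427 +- 0.089 kBT
```

The fast component is the one-bond dwell, the slow one the two-bond dwell;
their log-ratio says the second bond contributes about 2.4 k<sub>B</sub>T of
stabilization in a matched (C18) bilayer.

Run the bundled reference analysis — the per-bilayer dwell-time and
height-spectroscopy measurements fed through the same estimators and
extrapolated to zero mismatch:

```r
rep <- replicate_reference_analysis()
rep$energies
#>   lipid dG_diff dG_diff_se dG_asso_eq3
#> 1   C14   -3.26       0.38       -2.99
#> 2   C16   -2.55       0.38       -3.17
#> 3   C18   -2.30       0.17       -3.28
#> 4   C20   -3.22       0.18       -2.95

rep$dG_PP_diff$intercept   # -2.34 kBT : membrane-independent per-bond energy
rep$dG_PP_asso$intercept   # -6.87 kBT : membrane-independent association energy
rep$D_U0$intercept         #  0.69 um^2/s : diffusion at zero mismatch
rep$contacts$value         #  2.94 : mean bonds per array-bound molecule
```

Bond formation is *more* favorable in mismatched bilayers (C14/C20,
≈ −3.2 k<sub>B</sub>T) than in matched ones (≈ −2.3), while overall
association is most favorable near matching — the signature of
membrane-mediated interactions. Elastic theory reproduces the microscopic
side of this:

```r
b <- bilayer_spec(14)
b
#> bilayer_spec: C14  l = 24.0 A  K_A = 58.0 kBT/nm^2  kappa_b = 20.0 kBT  lambda = 1.19 nm

local_configuration_energies("clover_leaf", b, h = b$lambda_nm / 4)
#> local_config_energies (clover_leaf, u0 = 2.30 A, a = 6.70 nm)
#>   psi      : 4.363  8.178  12.260  15.317 kBT
#>   psi_norm : 1.00  1.87  2.81  3.51

barrier_height(10, 1e9)
#> energy_estimate (barrier): 23.026 kBT
```

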