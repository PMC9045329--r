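# methanokin

Kinetic metabolic modeling of methanogen growth, and what it says about the
Monod equation.

`methanokin` implements a thermodynamically constrained kinetic/stoichiometric
hybrid model of *Methanosarcina barkeri* growing on methanol, and the
growth-kinetic analyses built on top of it. It is aimed at systems biologists
and geomicrobiologists who want to study how a phenomenological growth law —
the Monod equation — emerges (and fails to emerge) from an explicit
methanogenesis network.

## The model

The cell is a 1-µm sphere with a cytoplasm and a membrane compartment.
Methanol, CO₂ and CH₄ exchange with the environment by diffusion
(J = 4πDr·ΔC); 16 enzymes of the methylotrophic methanogenesis pathway (9
cytoplasmic: MTA, MCR, MER, MTD, MCH, FTR, FMD, FRH, ACS/CODH; 7
membrane-associated: MTR, HDR, VHT, ECH, FPO, AHA, GERN) convert methanol to
CH₄ and CO₂ while building a membrane potential and regenerating ATP. Each
enzyme velocity follows a reversible multiplicative Michaelis–Menten law with
an explicit thermodynamic driving-force factor,

    v = W_prot · k · φ · (∏_S C_S/K_S) / D · [1 − exp(ΔG/(χRT))],
    ΔG = RT ln(Q/K_eq) + c_C F Δψ,

so every reaction stalls exactly at equilibrium and charge-translocating
steps feel the membrane potential. Metabolite dynamics obey mass balance
(dC/dt = (J + Σ c·v)/V) with conserved moiety pools (CoM, CoB, F420,
ferredoxin, methanophenazine, H₄SPT, methanofuran, CoA) eliminated through
their conservation laws, and dΔψ/dt = (F/C_m)·Σ c_C v. Biomass synthesis is
coupled by Herbert–Pirt logic: the pseudo-biomass flux is the ATP-synthase
surplus over maintenance divided by the ATP cost of biomass (0.14 mol ATP/g),
with proportional drains of reduced ferredoxin, reduced F420 and acetyl-CoA.

On top of the simulator the package provides:

* **steady states** by stiff integration with an optional Newton polish;
* **metabolic control analysis** — scaled flux control coefficients of every
  enzyme and diffusion process and flux response coefficients of every moiety
  pool, ε = (φ/µ)·∂µ/∂φ, by 1% perturbation and re-solution;
* **Monod analysis** — simulated growth curves µ(C); extraction of µ_max
  (rate at 1 M), K_M (concentration at µ_max/2) and the specific affinity α
  (initial slope below 10 µM); the alternative Monod form
  µ = µ_max·αC/(µ_max + αC); and a Gaussian-amended Monod law
  µ = alt_monod(C) + µ_o·exp[−π(ln(µ_max/αC)/β)²] fitted to the simulation;
* **proteome allocation** — Nelder–Mead maximization of the growth rate over
  the membrane-enzyme proteome budget (Σφ = 10%);
* **interchange** — a flat TSV parameter table and SBML Level 3 export/import.

The packaged default parameterization reproduces the laboratory-scale
behaviour of methanol-grown *M. barkeri*: a 135 mV membrane potential,
~0.7 µmolal dissolved H₂ with 98% of methyl-oxidation electrons carried by
hydrogen cycling, product yields of ≈0.67 CH₄ and ≈0.22 CO₂ per methanol,
and a hyperbolic growth curve with µ_max ≈ 1.0 d⁻¹, K_M ≈ 0.4 mM and
α ≈ 1.6×10³ M⁻¹d⁻¹. Every fixture value is flagged `printed` (fixed from
published measurements) or `calibrated` (tuned once so the assembled model
reproduces the reference steady state; see `tools/calibrate.R`).

## Worked example

```r
library(methanokin)

model <- build_network(fixture_barkeri())
model
#> <mb_network>
#>   35 metabolites in 3 compartments, 8 moiety pools
#>   21 reactions (16 enzymatic, 2 pseudo) + 3 diffusion processes
#>   external methanol: 100 mM

ss <- steady_state(model, methanol = 0.1, polish = TRUE)
ss
#> <mb_steady_state>
#>   methanol: 100 mM   converged: TRUE (max rel. dC/dt = 4.99e-12 s-1)
#>   membrane potential: 135.0 mV
#>   mu = 0.9985 d-1   mu_net = 0.9982 d-1

str(validation_summary(ss, model))
#> List of 9
#>  $ psi_mV            : num 135
#>  $ h2_uM             : num 0.7
#>  $ ch4_per_methanol  : num 0.674
#>  $ co2_per_methanol  : num 0.217
#>  $ h2_electron_share : num 0.98
#>  $ delta_g_min_kj    : num -31
#>  $ delta_g_max_kj    : num -0.02
#>  $ km_census_fraction: num 0.824
#>  $ mu_per_day        : num 0.999
```

The membrane potential, dissolved H₂, electron-routing share, product yields
and the spread of reaction free energies (−31 kJ/mol at methyl-CoM reduction
down to near-equilibrium cyclohydrolase and antiporter steps) are the model's
steady-state validation diagnostics; ~82% of (metabolite, K_m) pairs sit
above their Michaelis constants.

The growth curve and its phenomenological fit:

```r
curve <- growth_curve(model)          # 1 uM .. 1 M, 16 points per decade
fit <- monod_fit(curve)
fit
#> <monod_fit>
#>   mu_max = 1 d-1 (at 1 M)   K_M = 0.3995 mM   alpha = 1600 /M/d
#>   amendment: mu_o = 0.1679, beta = 1.68 (C < mu_max/alpha) / 4.34

coef(fit)[c("mu_max", "k_m", "alpha")]
plot(fit)                             # simulated vs Monod vs amended forms
```

Note that K_M (0.40 mM) is well below µ_max/α (0.625 mM): the simulated
curve rises *faster* than the Monod law through the transition, which is why
the plain Monod form misses the low-concentration limb by ~56% at 1 µM and
the alternative form by ~23% near half-saturation. Control analysis locates
the cause:

```r
flux_control_coefficient(model, "MTA", methanol = 1e-4)   # 0.95
flux_control_coefficient(model, "MCR", methanol = 1.5e-2) # 0.96
response_coefficient(model, "CoM", methanol = 1e-6)       # 0.92
response_coefficient(model, "CoM", methanol = 0.1)        # 0.31
```

The methanol:CoM methyltransferase dominates growth control below ~0.2 mM,
the methyl-CoM reductase above ~15 mM (crossover near 0.7 mM), and the
coenzyme M moiety is the rate-determining metabolite pool throughout — the
signature of a substrate-dependent shift between two rate-determining
reactions rather than a single Michaelis–Menten bottleneck.

## Layout

* `R/` — network model, kinetics, ODE/steady-state machinery, growth
  coupling, MCA, Monod analysis, diagnostics, toys, allocation, SBML/TSV IO.
* `inst/extdata/barkeri_params.tsv` — the packaged default parameter table.
* `tools/calibrate.R` — regenerates the parameter table from the documented
  design (provenance of every calibrated number).
* `vignettes/methanokin-methods.Rmd` — the model, its assumptions, numerical
  choices and limitations.
* `tests/testthat/` — unit, property and acceptance suites.
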