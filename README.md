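# defenseEcology

Eco-evolutionary modeling of prokaryotic antivirus defense: when should a
bacterium or archaeon invest in **immunity** (clearing virus from the cell —
restriction-modification, CRISPR-Cas, BREX, ...) versus **programmed cell
death** (PCD / abortive infection — destroying the infected cell before any
virion escapes)? Immunity saves the individual; PCD saves the neighbors.
The package is aimed at researchers in microbial eco-evolutionary dynamics
and comparative genomics of defense systems.

## What it implements

**Chemostat model.** A host population in a chemostat diluted at rate *B*
with influent nutrient φ₀ and virus ψ₀, described by a state matrix
*n(p, q)* over cell volume *p* and intracellular virion count *q*
(concentration ρ = q·p₀/(Q_max·p), normalized so a newborn cell holding
Q_max = 1000 virions is at ρ = 1). Per-cell processes: growth
A(1−r/E)·φ·p with division at 2p₀; infection of virus-free cells only
(superinfection exclusion) at rate C·ψ·p; per-virion replication at rate
*F*; immunity clearance at rate r·p at growth cost 1−r/E; lysis with
hazard (ρ/(T−ρ))^G releasing all virions; PCD — self-destruction without
release — once ρ ≥ 1−a. A defense strategy is the pair (a, r).

**Strategy optimization.** Equilibrium fitness N\* over the (a, r/E) grid,
nested refinement of the optimum, PCD-sensitivity
S = 1 − N\*(a=0, r_opt)/N\*(a_opt, r_opt) with the 0.1 sensitivity
classifier, and sweeps of ψ₀, C, E, F tracking optimal-investment trends.

**Competition & metapopulation.** Deterministic altruist-vs-cheater
competition through shared media; expected-progeny-loss maps (what a cell
forfeits by committing PCD); and a stochastic ensemble of chemostat patches
with size-proportional migration and patch birth–death, in which PCD can
fix globally despite its local cost (Simpson's paradox).

**Comparative-genomics statistics.** Genomic investment fractions from
annotation tables (interval-union spans / genome length); maximum-likelihood
power-law regression I_PCD = β·I_Imm^α with lognormal noise and BIC
comparison against α = 1 and α = 0; rank-abundance stratification of
species into consistently high-/low-abundant groups, Mann–Whitney group
comparisons, and deviation-from-genome-size quadrant analysis.

**Synthetic data.** Generators with serialized ground truth for all
statistical inputs (planted power laws, planted abundance groups with an
optional genome-size confound, random null gene profiles).

## Worked example

The reference ecology is the gut-microbiome-like parameter set used for the
fixation analysis; `defense_strategy(0.98716, 0.00584)` is the published
optimal strategy for it.

```r
library(defenseEcology)
pars <- chemostat_params()
pars
#> Chemostat ecology
#>   growth A = 28, dilution B = 0.05, uptake C = 1e-08
#>   immunity cost scale E = 0.0125, replication F = 4
#>   lysis G = 1, T = 1; influent phi0 = 1, psi0 = 1e+08
#>   discretization p0 = 10, Q_max = 1000; MOI proxy C*psi0 = 1

eq <- run_to_equilibrium(pars, defense_strategy(a = 0.98716, r = 0.00584))
eq
#> Chemostat equilibrium
#>   strategy a = 0.98716, r = 0.00584 (r/E = 0.4672)
#>   N* = 2382.38 cells, V* = 4.65385e+06, phi* = 0.5177, psi* = 9.921e+07
#>   t = 154 (converged, residual 9.86e-07)
```

The population persists far below the virus-free carrying capacity
(~1.9e6 cells), virus-limited: ψ\* stays near the influent concentration
and nutrient is only half depleted — each surviving lineage is continually
reinfected and saved by clearance or sacrificed by PCD. Strategies with no
immunity (r = 0), full immunity (r = E), no PCD under these conditions
(a = 0) or hair-trigger PCD (a = 1) all go extinct: the optimum is interior
in both defense dimensions (`scan_landscape()` + `refine_optimum()` locate
it at a ≈ 0.994, r/E ≈ 0.77 at the default lattice resolution).

Power-law machinery on synthetic genomes with a planted exponent:

```r
g <- generate_investment_dataset(alpha = 0.554, gamma = 1, n = 5000, seed = 1)
fit_power_law(g$pairs)
#> Power-law fit: I_PCD = 0.1474 * I_Imm^0.5524  (gamma = 0.9978)
#>   n = 5000 (0 zero-investment genomes dropped), loglik = -7084, BIC = 1.419e+04

compare_models(g$pairs)
#>     model    alpha       beta     gamma    loglik      BIC      dBIC
#> 1    free 0.552417 0.14744493 0.9978038 -7083.700 14192.95    0.0000
#> 2 alpha=1 1.000000 1.15988673 1.0985165 -7564.496 15146.03  953.0753
#> 3 alpha=0 0.000000 0.01156194 1.1477029 -7783.505 15584.04 1391.0935
```

The planted sublinear exponent (α̂ = 0.55 ± 0.02) is recovered and BIC
rejects both naive models (proportional and constant PCD investment) by
hundreds of points — the same model-comparison logic used on real
annotation data, where α < 1 means the PCD share of defense investment
falls as total investment (the viral-pressure proxy) rises.

See the methods vignette (`vignettes/defense-ecology-methods.Rmd`) for the
model's assumptions, numerical scheme, parameter defaults and limitations.

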