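---
title: "Modeling the immunity vs programmed-cell-death trade-off in prokaryotic antivirus defense"
author: "defenseEcology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the immunity vs programmed-cell-death trade-off}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(defenseEcology)
```

# The scientific problem

Prokaryotic antivirus defense systems fall into two broad functional
classes. *Immunity* systems (restriction-modification, CRISPR-Cas, BREX and
many others) clear virus from an infected cell, allowing recovery.
*Programmed cell death* (PCD, also called abortive infection) destroys the
infected cell before any virion is released, protecting neighbors at the
cost of the cell itself. Which mix of the two a genome should encode depends
on the ecology: viral pressure, carrying capacity, replication kinetics of
the virus, and the cost of immunity. This package implements a chemostat
model of that trade-off, the machinery to locate optimal defense strategies
and classify their sensitivity to PCD investment, deterministic
altruist-cheater competition, a stochastic structured-metapopulation
simulator in which PCD can fix despite its local cost (a Simpson's-paradox
mechanism), and the comparative-genomics statistics used to test the model's
predictions on annotation and rank-abundance data.

# The chemostat model

A well-mixed chemostat of fixed volume is diluted at rate $B$ by influent
media carrying nutrient at concentration $\phi_0$ and free virus at
concentration $\psi_0$. The cell population is described by a state matrix
$n(p, q)$ over cell volume $p$ and intracellular virion count $q$. Volume is
measured in the same natural units as virion capacity: a newborn cell has
volume $p_0$ and can hold at most $Q_{\max} = 1000$ virions, so the
intracellular virus concentration is $\rho = q\,p_0 / (Q_{\max}\, p)$ — a
newborn cell holding $Q_{\max}$ virions is at concentration 1, and a cell at
division size ($2p_0$) holding the same count is at concentration $1/2$.

Per-cell processes, with a defense strategy $(a, r)$:

* **Growth**: volume advances at rate $A\,(1 - r/E)\,\phi\,p$; a cell
  reaching $2 p_0$ with no virus divides into two newborn cells. Division is
  arrested by a single virion, but growth continues to division size.
* **Infection**: virus-free cells ($q = 0$) are infected at rate
  $C \psi p$, acquiring one virion; infected cells cannot be superinfected
  (superinfection exclusion), which makes the cell population a virion sink.
* **Replication**: intracellular virus replicates at per-virion rate $F$.
* **Immunity**: virions are cleared one at a time at rate $r\,p$,
  proportional to cell volume; investment $r \in [0, E]$ costs growth
  through the factor $1 - r/E$.
* **Lysis**: the hazard is $(\rho / (T - \rho))^{G}$ — zero for virus-free
  cells, strictly increasing, and divergent at the lethal threshold $T$
  where lysis is certain. A lysing cell releases all $q$ virions. Larger
  $G$ suppresses lysis far from the threshold, narrowing the burst-size
  distribution.
* **PCD**: a cell whose concentration reaches $1 - a$ self-destructs,
  releasing nothing; $a = 0$ disables PCD, $a = 1$ kills on the first
  virion. PCD is virus-triggered: uninfected cells never self-destruct.
* **Dilution**: all cells wash out at rate $B$, carrying their virions with
  them.

Nutrient is consumed at rate $C\phi$ per unit cell volume by all cells;
free virus is consumed by infection of virus-free cells and replenished by
lysis and the influent. The MOI proxy of an environment is $C\psi_0$, and
$1/C$ is proportional to the carrying capacity.

## Units and lattice resolution

The simulator tracks volume on a coarse lattice of `p0` substeps between
birth and division size (default `p0 = 10`) while keeping all *per-cell*
rates in the natural units above: the per-volume rates $C$, $r$ and the
immunity scale $E$ are converted internally by $Q_{\max}/p_0$. Division
timing is invariant to this choice (the time from $p_0$ to $2p_0$ at fixed
$\phi$ is $\ln 2 / (A\phi(1-r/E))$ for any lattice). Two quantities are
*not* resolution-invariant: the dispersion of the division-time
distribution (an Erlang chain with `p0` stages) and, at strongly
virus-limited equilibria, the absolute population size, which grows roughly
linearly with `p0` (the equilibrium sits at a near-critical balance that
amplifies small survival differences). Strategy-landscape *shapes* and
optimum locations are stable across `p0` = 10–40; absolute counts should be
compared only at fixed resolution.

The virion axis uses unit spacing up to `q_lin = 48` virions and geometric
spacing (factor 1.08) above, with transport rates divided by the node
spacing so the mean replication speed $Fq$ and the survival integral along
the climb to lysis are preserved. Strategies near the optimum (PCD
thresholds of tens of virions) live entirely in the unit-spaced region; the
coarse tail only carries PCD-incompetent lineages on their way to lysis.

## The integrator

The update is a uniformization (exponential-Euler) step: for every lattice
state the total outflow over $\Delta t$ is integrated exactly as
$n\,(1 - e^{-R \Delta t})$ and redistributed to destination states in
proportion to the individual rates. This preserves positivity for any step
size and handles the divergent lysis hazard near the lethal threshold
without step-size collapse. The scalar nutrient and virus pools relax
exactly toward their instantaneous fixed points, so at stationarity the
chemostat flux balances (e.g. $B(\phi_0 - \phi^*) = C\phi^* \sum p\,n^*$ in
the virus-free case) hold to machine precision by construction.

The step size adapts to the largest *transport* rate (growth, replication,
clearance, dilution) among states holding at least `floor_rel` of the
population. Pure-outflow boundary processes (the lysis hazard, replication
across the PCD/lysis boundary) and the single-jump infection flux are
excluded from the control: when faster than the step they are treated
quasi-statically, which leaves their *fluxes* asymptotically correct while
only the (negligible) standing mass of the fast states is biased. For
long runs the per-state redistribution coefficients are frozen over blocks
of `recalc = 16` steps and recomputed at the block's current
$\phi, \psi, \Delta t$; the exposed single-step function recomputes
everything exactly and is the reference the term-by-term oracle tests
check against.

Tolerances: a run is converged when population size, nutrient and virus
concentrations change by less than `tol` (default $10^{-6}$) per host
generation ($\ln 2 / (A\phi_0)$ time units, the paper-style normalization).
A population below $10^{-9}$ of its initial size is extinct with fitness 0.

## Initial conditions and bistability

Under strong viral pressure the model has an Allee structure: small
populations face the full influent virus concentration (every cell is
infected within a fraction of a generation) and die out, while larger
populations suppress free virus by consumption. Equilibrium fitness is
therefore defined for *established* populations: runs start from a
virus-free carrying-capacity-scale inoculum with nutrient at its
quasi-steady value and $\psi(0) = 0$, the virus entering through the
influent. At the reference gut-like ecology the surviving equilibria are
virus-limited and far below carrying capacity; both all-out strategies
($a$ or $r$ at their extremes) go extinct, producing an interior optimum in
both strategy dimensions.

# Fitness landscapes and PCD-sensitivity

Fitness is the equilibrium population size $N^*$. `scan_landscape()`
evaluates $N^*$ over an $(a, r/E)$ grid (default $21 \times 21$),
warm-starting neighbors; `refine_optimum()` localizes the peak by nested
5-point grid halving to a box width of $10^{-3}$ (ties toward smaller $a$,
then smaller $r$ — conservative toward "no PCD" on plateaus). Extinct
strategies keep fitness 0 so the landscape is a total function.

The equilibrium surface carries small ripples along $a$ (the PCD threshold
moves by single virions on the lattice), and near the optimum it is nearly
flat, so nested local refinement started from a coarse argmax can settle
on a secondary ripple. For comparisons *across* ecologies (parameter
sweeps) the package therefore locates optima by argmax on a fixed dense
grid — comparable by construction — rather than by per-ecology refinement;
refinement is reserved for localizing a single ecology's optimum from an
adequately fine coarse grid.

PCD-sensitivity is
$S = 1 - N^*(a{=}0, r_{\rm opt}) / N^*(a_{\rm opt}, r_{\rm opt})$, the
fraction of fitness lost by switching PCD off at fixed immunity; $S \ge
0.1$ classifies the ecology as PCD-sensitive (pronounced peak along the
PCD axis) versus a plateau. `sweep_parameter()` tracks
$(a_{\rm opt}, r_{\rm opt}/E, S)$ along one ecological axis
($\psi_0$, $C$, $E$ or $F$) and flags neighboring pairs in which both
ecologies are sensitive; optimal-investment trends are interpreted on
those pairs only, because on insensitive plateaus the argmax location is
numerically arbitrary.

# Competition and the expected cost of PCD

`run_competition()` couples an altruist (PCD-competent) and a cheater
(PCD-incompetent, same immunity) through shared nutrient and virus pools,
both seeded from the altruist equilibrium profile. Outcomes are classified
by the linear trend of the cheater fraction over the final half of the
trajectory, in units of change per host generation: |slope| below
$10^{-4}$ is neutrality; the sign decides otherwise. The paper-scale
observation behind neutrality is quantified by
`expected_progeny_loss()`: the expected number of future divisions a cell
at state $(p, q)$ would achieve, from a sparse first-passage solve of the
single-cell Markov chain at ambient $(\phi, \psi)$ — when PCD triggers only
at states whose expectation is already near zero, carrying the PCD allele
costs essentially nothing.

# The structured metapopulation

`simulate_metapopulation()` runs a Gillespie loop over three event types:
migration (exponential waiting times, mean $m$), patch birth (rate
$b(K-k)/K$) and patch death (rate $d$ per patch), with deterministic
within-patch dynamics between events. Migration draws the source patch
proportionally to its rounded population size — larger patches send more
migrants, which is the Simpson's-paradox engine — the destination uniformly
among other patches, and moves $n_m \sim \mathrm{Binomial}(N_i, f)$
individuals, split binomially by genotype. Patches are born with fresh
sterile media ($\psi = 0$; virus arrives via the influent within a few
dilution times), which is what makes colonization by small migrant batches
possible at all. Genotypes falling below half an individual in a patch go
locally extinct (the whole-individual reading of the rounding rule); global
fixation is declared when the global cheater fraction leaves
$[\epsilon, 1-\epsilon]$, $\epsilon = 10^{-3}$.

Defaults mirror a host-associated (gut-microbiome-like) scenario:
$K = 20$, $b = 0.4$, $d = 0.01$, $m = 1$, $f = 10^{-4}$, and an
established initial ensemble of $k_0 = K$ patches at cheater fraction 1/2.

Because absolute patch sizes scale with the volume-lattice resolution (see
above), the lattice must be fine enough that expected migration batches
$f \cdot N^*$ reach at least one whole individual — a functional
requirement of the migration process, not a tuning knob. Below that point
(e.g. `p0 = 10`, $N^* \approx 9\times10^3$, batches $\approx 0.8$) most
migration events carry nobody, colonization becomes a single-founder
genotype lottery, and the lottery is amplified by the founding bloom: a
founder in a fresh patch grows to the virus-free capacity (transiently
~100x the marginal equilibrium) and briefly dominates source selection,
broadcasting its genotype. Metapopulation analyses therefore use
`p0 = 20` by default ($N^* \approx 1.6\times10^4$, batches $\approx 1.6$),
the coarsest resolution at which the size-biased migration mechanism
operates. With it the paradox plays out cleanly: within each patch
cheaters hold or gain ground, yet cheater-rich patches are smaller, emit
fewer migrants and die unreplaced, so the global altruist fraction rises
to fixation — Simpson's paradox realized.

# Comparative-genomics statistics

Genomic investment in a defense class is the fraction of genome length (in
nucleotides) occupied by that class's systems, with overlapping
same-class annotations merged by interval union, and systems of unknown
character (`Undefined`) excluded. `fit_power_law()` fits
$I_{\rm PCD} = \beta I_{\rm Imm}^{\alpha}$ with lognormal noise by maximum
likelihood on natural logs (closed form: ordinary least squares with the
ML variance estimate); `compare_models()` contrasts the free fit against
$\alpha = 1$ (proportional investment) and $\alpha = 0$ (constant PCD
investment) by BIC, $k \ln n - 2\,\hat\ell$. Genomes with zero investment
in either class are excluded from the regression (the log model is
undefined there) and counted; the reported $\gamma$ is the standard
deviation of the underlying normal on the log scale. $\alpha < 1$ means
the PCD share of total defense investment falls as total investment — the
viral-pressure proxy — rises.

For abundance stratification, per-sample species ranks are oriented so
larger = more abundant, species present in fewer than 100 samples are
dropped, and a species is high-abundant if the first quartile of its
oriented ranks exceeds a threshold $T_a$, low-abundant if the third
quartile falls below it, intermediate otherwise. $T_a$ maximizes the size
of the smaller genome-backed group; candidate thresholds include
half-integers because with strict inequalities on both quartile rules an
attained integer threshold always strands the species sitting exactly on
it. Group comparisons use the two-sided Mann-Whitney test with tie
correction. The genome-size deviation analysis regresses per-system
nucleotide content on genome length across both groups jointly (a linear
expectation model, chosen for robustness), tests group residuals against
zero with the two-sided Wilcoxon signed-rank test, and reports signed log
p-values ($-\log_{10} p$ for overinvestment) with quadrant labels ordered
(low-group direction)-(high-group direction): a system overinvested only
in high-abundant species lands in "low-high".

# The synthetic-data generators

`generate_investment_dataset()` plants a known
$(\alpha, \beta, \gamma)$ power law under a lognormal immunity-investment
prior (median 1% of the genome, log-sd 1 — a realistic genomic defense
scale) and lognormal genome sizes (median 4 Mb, log-sd 0.3); pairs
violating $I_{\rm PCD} + I_{\rm Imm} < 1$ are redrawn. Spans are written as
real-valued `span_nt` so that the zero-noise dataset is recovered exactly
by the fitting pipeline. `generate_abundance_dataset()` plants
high/low/intermediate/rare species with controlled rank dispersion, an
optional multiplicative PCD-investment effect, and an optional genome-size
confound (larger genomes in the high group plus a size-proportional
content law with group offsets) constructed so the raw group comparison is
biased while the deviation analysis recovers the planted "low-high"
signal. `generate_random_gene_profiles()` provides size-proportional null
systems. Every generator serializes its truth (including the seed) next to
the data and regenerates byte-identically from it.

What the generators do *not* emulate: phylogenetic non-independence of
genomes, compositionality of relative abundances, annotation
false-positives/negatives, and correlated system co-occurrence. Passing
recovery tests on these data therefore validates the statistical
machinery, not the biological conclusions on real data.

# Problem sizes and numerical defaults

The packaged analyses run at desk scale: landscape scans use a
$21 \times 21$ grid with refinement to $10^{-3}$ (reference ecology) and
$11 \times 11$ grids with refinement to $2\times10^{-3}$ inside parameter
sweeps; metapopulation runs use `p0 = 10`, horizon 2000 time units and 5
seeds; power-law recovery uses $n = 5000$ genomes ($\gamma = 1$) and
60–100 replicates; abundance analyses use 40–60 species across 105–120
samples. Integrator defaults: `eta = 0.3` (target per-step outflow
fraction), `dt_max = 0.02`, convergence tolerance $10^{-6}$ per
generation. Halving `eta` changes equilibrium sizes by under 1% and
optimum locations by less than the refinement tolerance at the reference
ecology.

# Known limitations

* The printed source for two model expressions is typographically garbled;
  the package adopts the unique readings consistent with all stated limits
  (the lysis law $(\rho/(T-\rho))^G$ and the concentration
  $\rho = q\,p_0/(Q_{\max}p)$, i.e. $\rho = q/p$ in natural volume units).
* Absolute population sizes at virus-limited equilibria scale with the
  volume-lattice resolution (see above); cross-resolution comparisons are
  only meaningful for landscape shapes, trends and fractions.
* The equilibrium protocol (established inoculum, $\psi(0)=0$) is a
  documented package choice; under strong viral pressure the model is
  bistable and no initialization-free fitness definition exists.
* Deterministic within-patch dynamics ignore demographic noise at small
  patch sizes; the half-individual extinction cull is a coarse surrogate.
* Neutrality classification depends on the slope tolerance and window; the
  defaults (final 50%, $10^{-4}$ per generation) are the package's
  operational definition.
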