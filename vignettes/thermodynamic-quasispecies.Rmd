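---
title: "Thermodynamics of templated replication and quasispecies evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamics of templated replication and quasispecies evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quasitherm)
```

## The model

`quasitherm` connects the chemistry of template-directed nucleic-acid
synthesis to the population genetics of self-replicating sequences. Three
layers are stacked on top of each other:

1. **Single-molecule kinetics.** An elongating strand adds one nucleotide at
   a time against a template. The kinetics are specified by 16 forward rate
   constants $k_f(n'\mid n)$ (incoming base $n'$ against template base $n$,
   apparent second-order constants) and their excision counterparts. The
   reverse rates are tied to the forward ones by local detailed balance,
   $$k_b(n'\mid n) = \frac{k_f(n'\mid n)}{\gamma}\, e^{\Delta G(n'\mid n)},$$
   where $\gamma$ is the relative reaction quotient of the
   NTP $\to$ chain + PP$_i$ step ($\gamma = 1$ at equilibrium) and
   $\Delta G$ is the per-pair free energy in units of $k_BT$: one value $g$
   for the Watson–Crick pair and $g + \Delta\varepsilon$ for each of the
   three mismatches.

2. **Stationary elongation (mean field).** In the moving-front steady state
   the probability that a chain unit pairs $n'$ against $n$ is the
   generalized Boltzmann form
   $$q(n'\mid n) = \frac{k_f(n'\mid n)}{v_n + k_b(n'\mid n)},$$
   with the per-template-base velocity $v_n$ fixed by normalization
   $\sum_{n'} q(n'\mid n) = 1$ — a quartic with a single physically
   admissible root. Velocities and error rates are aggregated over the
   template composition with a *harmonic* mean (a chain crosses slow
   template bases one at a time), while the entropy production per monomer,
   $$A = \Big\langle \ln\gamma - \Delta G(n'\mid n) - \ln q(n'\mid n)
   \Big\rangle_{q},$$
   is an *arithmetic* template average: it is not a rate. $A$ is the
   thermodynamic force: the free-energy dissipation per added monomer,
   composed of chemical driving and of the sequence disorder written into
   the copy. This theory is exact whenever the rate set does not depend on
   the template base identity ("symmetric template models") and is a
   controlled approximation otherwise; the Gillespie simulator
   (`simulate_elongation()`) provides the exact reference in all cases.

3. **Quasispecies dynamics.** A genotype's replication rate is its
   elongation velocity divided by $2L$ (a replication *pair* is needed —
   only one polarity is catalytic — hence $2L$ nucleotide additions per
   reproductive cycle). On the single-peak landscape (master genotype with
   relative fitness $\sigma$) the infinite-population mean fitness has two
   branches, master-dominated and mutant-dominated, crossing at the error
   threshold $\varepsilon_2^* = 1 - \sigma^{-1/L}$ in the two-replication
   per-site error rate. The stochastic counterpart
   (`run_eigen_model()`) implements the replication/degradation reaction
   set with per-site mutation, exact Gillespie timing, and a lazily grown
   genotype ledger.

## The force as the organizing axis

The control parameter of a solution family is $\gamma$; each stationary
state *realizes* a force $A(\gamma)$ through its entropy production. Curves
and phase diagrams are indexed by that realized force, with $\gamma$
eliminated. This is the step that produces the fluid-like phase structure:
for high inverse fidelity $Q$ (the mismatch-to-match kinetic ratio),
$A(\gamma)$ is monotone and $v(A)$, $\varepsilon(A)$ are single-valued; for
low $Q$ a force window appears in which two stationary branches coexist — a
slow, error-prone state (the "gas" G) and a fast, accurate one (the
"liquid" L). When several branches share one force the higher-velocity
branch is taken as realized, since it produces entropy faster; the package
deliberately does not attempt a Maxwell-type equal-free-energy construction.
The locus where the L branch ceases to exist is the spinodal; it terminates
at a critical $Q$ above which the two fluids merge. Adding the error
threshold of the single-peak landscape draws the melting line, below which
a "crystalline" C phase — a stable master-dominated quasispecies — exists.
Where the error rate at the end of the L branch is already below the
threshold, the crystal loses stability directly against the gas
(sublimation); the point separating the two regimes is the triple point,
and `phase_features()` extracts it from that criterion rather than from
fragile contour intersections.

A note on bookkeeping: the *nominal* force of a condition, $\ln\gamma$, is
what an ideal reservoir at that composition would exert; it coincides with
the realized force only at equilibrium. Wherever a state must be produced
"at force $A$" (population runs, phase-diagram cells), the package inverts
the realized $A(\gamma)$, which is precisely the matching condition between
internal entropy production and external driving.

## Parameters, units, defaults

* `delta_eps` (default **0.5** $k_BT$): the equilibrium stability penalty of
  a terminal mismatch relative to the Watson–Crick pair. Duplex-terminus
  measurements on DNA and RNA place this around 0.3 kcal/mol near 310 K,
  i.e. roughly half a thermal unit — strikingly small compared with the
  kinetic discrimination of polymerases, which is the point of the theory.
* `g` (default `log(1 + 3*exp(-delta_eps))`): the concentration offset of
  the per-pair free energy. The default is the calibration at which the
  equilibrium pairing distribution is exactly the two-level Boltzmann
  distribution (ground state + 3 degenerate mismatch states), making the
  stationary velocity vanish at $\gamma = 1$. It is stored, not recomputed,
  so off-calibration values can be probed.
* `K_eq` (default **10**): equilibrium constant of the monomer-addition
  step, used only by the closed-system (starvation) bookkeeping. Because
  first-principles estimates of this constant are uncertain by orders of
  magnitude, every starvation conclusion is checked over a
  $10^{-1}$–$10^3$ scan (`starvation_threshold_map()`).
* Rates carry the units of the input table; simulated time is measured in
  those inverse units. Fitness on phase diagrams is
  $k_0\,\bar k\,v_{\mathrm{rel}}/(2L)$ times the landscape branch factor,
  where $v_{\mathrm{rel}} = v/\bar k$ is the *relative* velocity of the
  rescaled table: the $Q$ axis changes fidelity only, while the rate scale
  $\bar k$ belongs to the genotypes (the landscape). With this convention a
  flat landscape ($\sigma = 1$) has a monotone fitness–fidelity relation
  and no starvation threshold, as it should.
* Landscape defaults used in examples and checks: $L = 20$, $\sigma = 20$
  for phase structure and crystallization, $\sigma = 4$ for the
  quasispecies test case; populations of 300–1000 replicators.

## Packaged rate tables are synthetic

The five packaged tables (`load_fixture()`: nonenzymatic, R18 ribozyme,
poliovirus 3Dpol, Dpo4, pol-γ) are **synthetic illustrative stand-ins**,
not experimental values: constructed 16-rate tables whose aggregate
$(\bar k, Q)$ layout mirrors the qualitative picture of the named systems —
nonenzymatic chemistry orders of magnitude slower and less faithful
($Q = 0.1$) than any polymerase, the ribozyme intermediate ($Q = 0.03$,
near-critical), the protein polymerases fast and faithful
($Q \le 8\times10^{-3}$, deeply subcritical). Every file says so in its
`#eef` provenance header. Quantities that depend only on this qualitative
layout (the existence of the critical region between nonenzymatic and
protein-polymerase fidelities, the starvation threshold enclosing the
nonenzymatic $Q$) are meaningful; absolute coordinates are illustrative.

## What the generators emulate — and what they do not

Random tables (`random_rate_table()`) come in three nested classes: JC
(two parameters), symmetric-template (four), general (sixteen,
log-normal). Symmetric models are where the mean-field theory is provably
exact, so they anchor the simulator–theory cross-checks; general tables
probe the mean-field approximation the way heterogeneous real kinetics do.
Templates are i.i.d. uniform by default. Real replication differs in ways
the model deliberately omits: incorporation rates depend on the upstream
base pair (stalling after mismatches), templates have composition bias and
secondary structure, monomer pools are neither equimolar nor well mixed,
and genome-length changes (insertions/deletions) are excluded. Passing
checks therefore validate the theory's internal consistency and its
stationary-state logic, not the quantitative kinetics of any particular
experimental system.

## Numerical choices

* **Root finding.** The normalization quartic is solved per template base
  by bracketed bisection (`uniroot`) on $(-\min k_b,\ \sum k_f]$, where the
  residual is strictly decreasing, then polished by Newton to ~$10^{-12}$
  relative; failure to bracket raises an error rather than returning a
  spurious branch.
* **Branches and bistability.** Curves are swept in $\gamma$ (where the
  solution is always unique), then re-indexed by the realized force;
  monotone-in-$A$ segments become branches, with steps below $10^{-9}$
  relative treated as noise. Bistability = any force attained by two
  branches. The spinodal is read off as the low-force terminus of the
  branch that continues to $\gamma \to \infty$.
* **Realizing a state at a force.** Branch-wise linear interpolation on the
  swept curve proposes $\gamma$; a damped secant solve of
  $A(\gamma) = A_{\mathrm{target}}$ polishes it (closing the loop to
  $10^{-6}$), and the state is recomputed exactly.
* **Degenerate inputs.** Zero mismatch rates are representable only as the
  flagged output of `rescale_fidelity(, target_Q = 0)`; equilibrium
  ($\gamma = 1$ with calibrated $g$) yields $v = 0$ exactly and estimators
  that require net growth refuse to run. Elongation that shrinks back to
  zero length continues (the length-0 state simply has no excision
  reaction) unless the caller asks to stop there.
* **Quadrature.** The starvation average $\langle\bar w\rangle$ uses the
  trapezoidal rule on the stored $n$ grid (101 points by default), which is
  verified against adaptive quadrature on smooth cases.
* **Population kernel.** Genotypes are packed 2 bits/site into 64-bit
  codes (so $L \le 26$ through the numeric interface); the genotype ledger
  grows lazily and is compacted when mostly extinct. All randomness is R's
  own generator, so a seed makes any run bit-reproducible.

## Design choices that were genuinely open

* **Harmonic vs arithmetic averaging.** Velocity and error rates use the
  harmonic template average with the per-column summation done first; with
  that order, the far-from-equilibrium error bound is exactly
  $Q/(1+Q)$ with $Q$ itself a harmonic aggregate. The entropy production is
  arithmetic. The asymmetry is intentional: one is a rate, the other is not.
* **Constant-N ensemble for the closed-form comparison.** Starting the
  growth ensemble from a single founder leaves an $O(1)$ early-time gap
  between the ensemble-mean frequency and the deterministic two-type
  solution that no number of trajectories removes (a small-denominator
  effect). The ensemble check therefore runs the constant-N process at
  $N = 1000$ from the pure-master state, whose frequency dynamics obey the
  same closed form with $O(1/N)$ corrections. Both modes are available in
  `validate_against_closed_form()`.
* **Upstream context.** Rates are local (no dependence on the previously
  incorporated pair); the fixture format has no upstream dimension. This is
  a known simplification, kept because the stationary theory is built on it.
* **Error rate of a population event.** One simulated replication event
  stands for a full $\pm$-polarity pair, so the per-site mutation
  probability handed to the population kernel is the two-replication error
  rate $\varepsilon_2$ of the single-molecule theory at the ambient force.

## Problem sizes

The test suite and the acceptance script run at desk scale, chosen as the
sizes at which every stochastic check resolves its target within its error
bars: elongation runs of $10^5$ events on $10^5$-base templates; 20 random
symmetric models × 5 forces for the exactness property; ensembles of 100
constant-N trajectories ($L = 20$, $N = 1000$); six error rates spanning
the threshold at 4 replicates each; phase grids of 41×41 (tests) and 60×60
(acceptance script) with 151–201 points per $\gamma$ sweep;
crystallization pools of $N_0 = 300$ with 5 seeds. The whole suite runs in
about a minute on one CPU.

## Known limitations

Finite-length transients (the chain-length distribution before the moving
front forms) are not modeled; only base substitutions are considered, so
genome-length evolution is out of reach; the mean-field error rate for
strongly template-asymmetric tables is approximate (the simulator is the
arbiter); the constant-N process is a martingale, so very long runs drift
in $N$ and can go extinct — run lengths should be set in units of
population turnovers, as `run_crystallization()`'s examples do; and no
spatial structure or multi-species chemistry is included.
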