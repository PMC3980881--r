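---
title: "Chaotic multiquenching annealing: model, schedules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chaotic multiquenching annealing: model, schedules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmqa)
```

## The optimization problem

A peptide conformation is parameterized by its dihedral angles
$\sigma = (\sigma_1, \dots, \sigma_m)$, each on $(-180°, 180°]$: backbone
$\phi$ and $\psi$ at every residue, optionally the peptide-bond $\omega$
(held rigid at $180°$ by default), and the side-chain $\chi_k$ torsions.
The native structure is modelled as the global minimizer of a free-energy
surrogate $E(\sigma)$, so structure prediction becomes global optimization
of a highly multimodal function over a torus. The package implements a
three-phase annealer for this search:

1. **Multiquenching phase (MQP).** Starting from a very high temperature
   $T_0$, the temperature is cooled by the quadratic quench
   $T_{k+1} = \alpha_Q (1 - \tau) T_k$ with $\tau \leftarrow \tau^2$ after
   each Metropolis cycle. When $\tau$ converges (from $\tau_0 = 0.90$ it
   takes exactly 7 squarings to fall below $9\times10^{-4}$), one
   *chaotic local search* is run, $\tau$ is reset, and a new quench
   subphase begins. MQP ends at the crossover temperature
   $T_{\text{threshold}}$.
2. **Annealing phase (AP).** Classical simulated annealing with geometric
   cooling $T_{k+1} = \alpha_A T_k$ down toward $T_f$, with the same
   uniform single-coordinate proposal and Boltzmann acceptance
   $\min\{1, e^{-\Delta E / T}\}$ (ties $\Delta E = 0$ are accepted).
3. **Dynamic equilibrium (DEP).** Once $T \le T_{fa}$, the end-of-cycle
   energies stream into a sliding window of $n$ points and a least-squares
   line $E = a x + b$ is fitted with the closed form
   $a = [12\sum x_i E_i - 6(n-1)\sum E_i]/(n^3 - n)$, $x_i = 0,\dots,n-1$.
   The run stops as soon as $|a| < \varepsilon$: the trace has flattened
   and further cooling is not buying improvement.

Two baselines share every component: `run_mqa_dep()` is the same engine
with the chaotic search disabled, and `run_csa()` is single-phase
geometric annealing from $T_0$ to $T_f$ with no quench, chaos or
equilibrium detection.

## The chaotic driver

The local search is driven by one of four sine maps with singularities at
the ends of the unit interval,

$$f_1(x) = \sin(1/x),\quad
  f_2(x) = \sin\!\Big(\frac{1}{x}\cdot\frac{1}{1-x}\Big),\quad
  f_3(x) = \sin\!\Big(\frac{100}{x}\cdot\frac{1}{1-x}\Big),\quad
  f_4(x) = \sin(1/x)\,\sin\!\Big(\frac{5}{1-x}\Big),$$

selected as `chaos.map` $\in$ {M1, M2, M3, M4}. Near the singular points
these oscillate with unbounded frequency, which is what makes them useful
as bounded, erratic step generators. The maps are curves, not dynamical
systems, so an iteration rule is needed; this package uses
$x_{k+1} = \mathrm{fold}(|f(x_k)|)$ confined to
$(\text{guard}, 1-\text{guard})$ with guard $10^{-6}$, re-seeding
deterministically from the run's random stream if an iterate lands in a
guard region or on a fixed point. This choice gives a bounded,
reproducible driver, which is all the greedy search requires; the package
makes no claim of formal chaoticity (e.g. positive Lyapunov exponents)
for the iterated scheme. Each chaotic step perturbs one uniformly chosen
coordinate by $y \cdot A$ degrees, $y = f(x) \in [-1, 1]$, amplitude
$A = 90°$ by default; the step is kept only if it strictly lowers the
energy of the best-so-far solution. The surrounding Metropolis state is
saved and restored, so the chaotic search refines the reported minimum
without steering the chain. One chaos state persists across firings
within a run, keeping replay determinism.

## Temperature tuning and defaults

$T_0$ and $T_f$ are tuned analytically from the landscape by inverting
the Boltzmann relation: a random walk of `tune_samples` (default $100m$)
single-coordinate probes records the positive deteriorations; then
$T_0 = -\Delta Z_{\max} / \ln p_{\text{hot}}$ and
$T_f = -\Delta Z_{\min} / \ln p_{\text{cold}}$ with
$p_{\text{hot}} = 0.95$ and $p_{\text{cold}} = 0.01$, so the start
accepts almost everything and the end almost nothing. A constant
landscape has no deterioration and is rejected with a request for more
samples rather than guessed at.

Parameters that matter, with units and defaults:

| parameter | default | meaning |
|---|---|---|
| `alpha_quenching` | 0.85 | quench decrement factor, in $[0.7, 1)$ |
| `alpha_annealing` | 0.95 | annealing decrement factor, in $[0.7, 1)$ |
| `tau0`, `tau_final` | 0.90, 0.0009 | quadratic quench parameter and its convergence cutoff |
| `t_threshold_frac` | $10^{-6}$ | $T_{\text{threshold}}$ as a fraction of $T_0$ |
| `t_fa_frac` | 10 | $T_{fa}$ as a multiple of $T_f$ |
| `L_per_var` | 10 | Metropolis proposals per variable per cycle |
| `M_chaot` | $m$ | chaotic steps per local-search firing |
| `dep_window`, `dep_epsilon` | 30, $10^{-3}$ | equilibrium window (cycles) and slope threshold (energy/cycle) |

Three of these deserve justification, since the design was genuinely
open:

* **Crossover placement.** With $\tau_0 = 0.90$ the first quench cycle
  removes 90% of the temperature, and one full 7-cycle subphase divides
  it by roughly $10^3$. A crossover at a modest fraction of $T_0$ would
  therefore end MQP within a single cycle and the chaotic search would
  never fire. The default $T_{\text{threshold}} = 10^{-6}\,T_0$ gives
  about two complete subphases — two chaotic-search firings — before
  annealing begins, which is the smallest schedule in which the
  multiquenching architecture is actually exercised. On landscapes whose
  deterioration range is narrow the fraction is raised to $T_{fa}$ so the
  ordering $T_f < T_{fa} \le T_{\text{threshold}} < T_0$ always holds.
* **Annealing entry.** The quench step overshoots (its last factor can
  be $\approx 0.085$), so AP explicitly re-enters at
  $T_{\text{threshold}}$ rather than at the overshot temperature;
  otherwise the annealing phase could be skipped entirely.
* **Cycle length and window.** $L = 10m$ proposals per temperature is
  standard dimension-scaled practice; the 30-cycle window and
  $\varepsilon = 10^{-3}$ make the stopping rule insensitive to
  single-cycle noise while still ending runs that have equilibrated
  (both configurable). The energy streamed to the window is the current
  chain energy $E_i$, not the running minimum, since the minimum is
  non-increasing by construction and would bias the slope toward zero.

`alpha_quenching = 0.85`, `tau0 = 0.90` and `tau_final = 0.0009` are the
standard settings for this family of schedules, and the annealing factor
is conventionally swept over $[0.75, 0.95]$ (see `sweep_grid()`).

## The reduced energy model

The full atomistic force fields used for peptide work (ECEPP/2-3, AMBER,
CHARMM) are deliberately out of scope; the package ships a *reduced
surrogate* that preserves the two features the optimizer cares about —
the dimension and coupling structure of the search space, and the
four-component anatomy of the energy — without importing an entire force
field. Each residue contributes backbone N, CA, C, O atoms, a CB for
non-glycine residues, and one generic pseudo-atom per $\chi$ variable,
placed by natural extension with fixed bond lengths and angles
(`build_coordinates()`); a virtual carbonyl carbon anchors the N-terminus
so that $\phi_1$ is geometrically meaningful, and the C-terminal $\psi$
is realized through the carbonyl oxygen. Both terminal angles are
therefore counted, which together with the package's side-chain table
(heavy-atom $\chi$ plus terminal hydroxyl/thiol/methyl rotors) gives the
pentapeptide YGGFM its reference dimension $m = 19$. The energy is

$$E = \underbrace{\sum_{ij} \frac{A_{ij}}{r_{ij}^{12}} - \frac{B_{ij}}{r_{ij}^{6}}}_{\text{Lennard-Jones}}
  + \underbrace{\sum_{ij} \frac{332\, q_i q_j}{D\, r_{ij}}}_{\text{electrostatic}}
  + \underbrace{\sum_k \frac{U_0}{2}\big(1 + \cos(n\theta_k - \theta_0)\big)}_{\text{torsion}}
  + \underbrace{\sum_{N\cdots O} \frac{A'}{r^{12}} - \frac{B'}{r^{10}}}_{\text{hydrogen bond}}$$

over non-excluded pairs (1-2 and 1-3 excluded; backbone N···O pairs at
residue separation $\ge 2$ move from the 12-6 to the 12-10 sum). All
constants live in the versioned parameter file
`inst/extdata/energy_params.yaml`. Absolute energies from this surrogate
are **not** comparable with any published force field, and no claim is
made about them; they exist to give the optimizer a realistic search
landscape. Pairs closer than $10^{-6}$ Å are charged a large finite
penalty instead of overflowing.

## The planted landscape: what it emulates and what it does not

Validation uses a synthetic objective with a certified global minimum:
a separable cosine well $\sum_i (1 - \cos(\sigma_i - \sigma^*_i))$ plus
`n_traps` compactly supported two-coordinate bumps subtracted at centers
135-180° away from the optimum. Each trap depth is pinned strictly
between the largest single-coordinate escape gain (below which it would
not be a local minimum) and the minimum of the base energy over the
trap's support (above which the total could dip below zero); traps use
disjoint coordinate pairs. Together these bounds *prove* that the global
minimum is exactly 0, uniquely at $\sigma^*$, and that every trap is a
genuine local minimum — no numerical search is needed to certify the
ground truth, though the construction spot-checks itself.

The landscape emulates the features that drive annealer behaviour on
peptides: periodic coordinates, a funnel toward the optimum, and local
minima requiring coordinated two-variable escapes. It does *not* emulate
the strong inter-variable coupling, clash walls or frustrated pair terms
of a real energy surface, so recovery results on it demonstrate correct
engine mechanics and schedule behaviour, not predictive power on real
proteins.

## Numerical choices and conventions

* Angles are degrees on $(-180°, 180°]$ throughout; wrapping is circular
  ($179° + 2° \mapsto -179°$, and $-180°$ normalizes to $+180°$).
* Coordinates are in Å; dihedrals follow the IUPAC sign convention; the
  torsion-to-Cartesian round trip is exact to $<10^{-6}$ degrees.
* Ties $\Delta E = 0$ are accepted ($e^0 = 1$ beats any uniform draw).
* The Metropolis proposal redraws one angle fresh and uniformly rather
  than adding a bounded delta — the simplest uniform perturbation, and
  the one under which the analytic tuning probes match the run-time
  proposal distribution.
* Evaluation counting is uniform: tuning probes, Metropolis proposals
  and chaotic-search probes all count against the same budget, which is
  how `compare_variants()` matches budgets across variants (the
  classical baseline's cycle length is scaled so its schedule spends the
  chaotic run's budget).
* All runs are pure functions of (objective, config, seed). A
  consequence worth knowing: in paired-seed comparisons the chaotic and
  non-chaotic variants share most of their random stream, and because
  redraw proposals overwrite coordinates wholesale the two chains often
  *coalesce* (identical traces after a divergence window). This is the
  common-random-numbers effect, it is expected, and it makes the paired
  comparison conservative rather than biased.
* `dep_slope()`'s closed form is algebraically identical to the general
  least-squares slope for equally spaced abscissae; the suite verifies
  agreement to $10^{-9}$ over a thousand random windows.

## Problem sizes used in the shipped checks

The test suite and the acceptance script exercise: the $m = 19$,
5-trap planted landscape (10 seeds of full three-phase runs, each a few
seconds); paired-seed comparisons of the three variants at matched
budgets (10 triples); $10^4$-proposal acceptance calibrations; and
thousand-window least-squares identities. These sizes were chosen so the
full battery reruns in well under a minute of compute per component
while leaving every statistical check with comfortable margins (e.g.
binomial $3\sigma$ bands on acceptance rates).

## Known limitations

* The reduced energy model is a surrogate: its minima are not native
  structures and its kcal/mol scale is package-specific.
* The side-chain pseudo-atom chain ignores branching (Ile, Thr, Val
  branches collapse onto one chain) and rings are approximated by their
  torsion count.
* The chaotic iteration rule is a documented package choice layered on
  maps that are published only as curves; other rules would give other
  (equally valid) drivers.
* Quench subphase count is controlled indirectly through
  `t_threshold_frac`; on landscapes with very narrow deterioration
  ranges MQP may complete fewer subphases than requested because the
  crossover is clamped above $T_{fa}$.
* No reheating, parallel tempering or restarts; the annealer is
  single-trajectory by design.
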