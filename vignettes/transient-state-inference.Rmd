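---
title: "Inferring active reactions in the transient state from metabolite concentration shifts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring active reactions in the transient state}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ShiftFlux)
```

## The problem

Quantitative metabolomics often yields two snapshots of a cell's metabolite
pools — before and after a perturbation such as a substrate pulse — without
resolving the transition between them. ShiftFlux asks which reactions of a
genome-scale stoichiometric model were most plausibly active *during* that
unobserved transient, using only the measured differences in metabolite
concentrations and the network's stoichiometry.

The central quantity is the moles-passed vector $\varphi$: for each reaction
$j$, $\varphi_j \ge 0$ is the time-integral of its rate over the transition
interval, i.e. the total moles converted. Reversible reactions are split
beforehand into a forward and a backward copy (ids suffixed `_R`), so a
direction is inferred for every active reversible reaction, and at most one
direction may be active per solution. Stoichiometry links $\varphi$ to the
net change of every metabolite: the predicted variation is $S\varphi$, where
$S$ is the metabolites-by-reactions stoichiometric matrix.

Measured metabolites (the set $X$) constrain their components of $S\varphi$
to an interval $[\Delta^{\min}_i, \Delta^{\max}_i]$ of moles accumulated
(positive) or depleted (negative). Each interval must be strictly one-signed:
a change whose sign is uncertain carries no usable direction information, and
the optimisation below relies on the sign being known. Non-measured
metabolites ($\bar X$) receive a relaxation $[-\epsilon, +\epsilon]$ — we do
not know whether they changed, but unlimited silent accumulation would make
the inference vacuous.

## The optimisation

Among all feasible moles-passed vectors we prefer (a) few active reactions —
the parsimonious assumption that a shift uses a small part of the network —
and (b) little variation parked on non-measured metabolites, while
(c) explaining as much measured change as possible. With binary support
variables $y_j$ ($y_j = 0 \iff \varphi_j = 0$) the program is

$$
\min_{\varphi, y}\;
\lambda \sum_j y_j
\;+\; (1-\lambda) \sum_{i \in \bar X} |(S\varphi)_i|
\;-\; (1-\lambda) \sum_{i \in X} |(S\varphi)_i|
$$

subject to $\Delta^{\min} \le S\varphi \le \Delta^{\max}$,
$0 \le \varphi_j \le u_j$, $y_j + y_{\bar j} \le 1$ for every split pair, and
the indicator link between $y$ and $\varphi$. The weight
$\lambda \in (0, 1)$ balances parsimony against connectivity: small
$\lambda$ (0.1 is the conventional working value) favours connected routes
that carry measured change between measured metabolites; large $\lambda$
yields smaller, more local, often disconnected solutions. $\lambda = 1$ is
exposed as a separate cardinality-only mode (the continuous terms vanish);
it is mainly useful for oracle testing.

Two linearisation details matter. The maximised measured term is non-convex
in general; it is linear here only because measured intervals are strictly
one-signed, so $|(S\varphi)_i| = s_i (S\varphi)_i$ with the precomputed sign
$s_i$ — which is exactly why zero-spanning inputs are rejected upstream. The
minimised non-measured term uses standard epigraph auxiliaries
$a_i \ge \pm(S\varphi)_i$; their positive objective coefficient forces them
to bind at any optimum with $\lambda < 1$.

The indicator $y_j = 0 \iff \varphi_j = 0$ is realised as the constraint
pair $\varphi_j \le u_j y_j$ and $\varphi_j \ge \theta y_j$ with a minimum
activity $\theta > 0$ (default $10^{-4}$, in the same moles unit as
$\varphi$). $\theta$ is a modelling knob: it excludes supports that are
active only through vanishing flux. Support membership is read back with
threshold $\tau = \theta / 2$ so numerical dust never creates spurious
active reactions.

## Sources, sinks and boundary blocking

Reactions with only substrates or only products (and reactions touching
species flagged as outside the system) move matter across the model
boundary, where it escapes the objective. They are blocked by default —
their cap is set to zero, keeping indices stable — via
`blockBoundary()`. Imbalances that would leave the system then show up as
accumulation on the boundary reaction's substrates, which is informative
rather than lost. Where a genuine external pool exists (the pulsed
substrate, oxygen, biomass), it is declared a virtual source or sink: a
source lowers the metabolite's $\Delta^{\min}$ to $-M$, a sink raises
$\Delta^{\max}$ to $+M$. The default magnitude $M$ is ten times the largest
measured $|\Delta|$, keeping the virtual pool on the same scale as the data;
it is overridable per declaration. Note that a source declared on a measured
metabolite deliberately widens its interval across zero, so the
sign-linearisation guarantee no longer applies to that one metabolite.

## Enumeration of alternate optima

Metabolic networks are redundant: several reaction sets can explain the same
measurements. After each solve, the support $y^*$ is excluded with the
integer cut $\sum_{j : y^*_j = 1} y_j \le \sum_j y^*_j - 1$ and the program
is re-solved. The cut forbids the exact support *and every superset of it* —
a deliberate property of this constraint form: a superset would re-explain
the data with strictly more machinery, so nothing interpretable is lost.
The objective is *not* fixed to the first optimum, so later solutions may be
slightly worse; with a zero MIP gap the objective sequence is non-decreasing
because the feasible region only shrinks. An optional `max_degradation`
fraction stops enumeration once solutions worsen beyond a user budget.
Iterations stopped at the gap or time limit still record and cut their
(possibly suboptimal) solution, so enumeration always makes progress.

Across the enumerated set, `occurrenceTable()` reports for each (original
reaction, direction) the fraction of solutions using it — the package's main
biological readout — and `exportEscher()` writes it in the JSON reaction-data
form that pathway-map viewers consume (forward positive, reverse negative).

## Robustness to the measured panel

`robustnessAnalysis()` re-runs enumeration with measured metabolites
excluded and reports the distance between the reduced and full occurrence
tables. The distance is the mean, over the union of direction-resolved
reactions, of the absolute occurrence difference in percentage points, with
rows absent from one table counted as 0% (a `max` aggregation is available
by flag — the mean is the default because a single swapped reaction should
not dominate the score). A reduced problem that becomes infeasible predicts
nothing active, and is scored as an all-zero table rather than discarded:
losing feasibility is the strongest possible dependence on the excluded
measurement and should register as a large distance.

## Deriving intervals from baseline and fold change

When the data arrive as a baseline concentration (mean $\pm$ replicate
deviation) and a fold change for the second state,
`deltaFromBaseline()` converts them with the convention
$\Delta = m(f - 1) \pm d$: the centre is the baseline mean times the fold
change minus one, and the replicate deviation — reported for the baseline
only — is attached additively to both ends. Alternative error-propagation
conventions (e.g. multiplicative) would be defensible; the convention is
therefore isolated in this one function so it can be swapped without
touching anything else. Intervals that span zero after the conversion are
rejected as non-significant, consistent with the sign requirement above.

## Parameters at a glance

| parameter | meaning | unit | default |
|---|---|---|---|
| `lambda` | parsimony weight in the objective | — | 0.1 (none hard-wired) |
| `epsilon` | allowed variation of non-measured metabolites | moles | 0 |
| `theta` | minimum moles passed through an active reaction | moles | 1e-4 |
| `u_default` | cap on moles passed when the model gives no finite bound | moles | 1000 |
| `mip_gap` | relative optimality gap at which a solve may stop | — | 0 |
| `time_limit_s` | wall-clock budget per solve | s | Inf |
| source/sink `M` | virtual pool magnitude | moles | 10 × largest measured change |

`epsilon` admits per-metabolite overrides (asymmetric intervals), covering
the practice of capping non-measured variation at the largest measured
change. `u_default` matters only when the SBML model carries no finite flux
bounds; its magnitude is a free parameter of the method, and the solver's
presolve tightens it against the data before branching, so results are
insensitive to its exact value as long as it is not binding.

## Solver and numerical choices

The program is solved by a deterministic, single-threaded branch-and-bound
over the binary supports. Each node is bounded by the LP relaxation
($y$ relaxed to $[0,1]$); branching picks the most fractional support
variable and explores the branch nearest its relaxation value first. Before
branching, a presolve pass maximises each $\varphi_j$ over the row polytope
and uses the optimum as a tightened cap — with generic caps like 1000 the
indicator relaxation $y_j \ge \varphi_j / u_j$ is nearly vacuous, and this
single step is what makes desk-scale instances solve in milliseconds. A
rounding heuristic (support of the root relaxation, larger member kept per
split pair) supplies an early incumbent. The LP core is a compact two-phase
dense primal simplex with Bland's anti-cycling rule, written for the small
dense relaxations this package generates; determinism and a trustworthy
infeasibility verdict were the design goals, not large-scale speed.

Tolerances: feasibility checks use $10^{-6}$; LP reduced-cost and ratio
tests use scale-adjusted $10^{-9}$; brute-force ties are declared within
$10^{-6}$. Ties between alternative optima are genuinely solver-dependent
and never asserted on — tests compare solution sets, or objective sequences
when the exhaustive oracle reports a tie. The oracle breaks ties
lexicographically by reaction index; that convention is test-only and not a
property of the method. Infeasible instances are diagnosed by relaxing one
measured metabolite at a time and reporting those whose relaxation restores
feasibility.

One notational remark: the reaction-count term sums over all *split*
reactions. After splitting, at most one member of each pair can be active,
so the term counts directed active reactions, which is the intended meaning.

## What the synthetic generator does and does not emulate

`makeToyNetwork()` provides chains, branches, cycles, a reversible pair and
seeded random connected unit-stoichiometry networks;
`makePlantedInstance()` plants a ground-truth $\varphi^\*$ on a chosen
support, computes the true variation $S\varphi^\*$, and derives measured
intervals ($\pm$ a noise half-width) for a sampled subset of the affected
metabolites. This emulates the structure of the inference problem — interval
measurements consistent with an unknown sparse moles-passed vector,
unmeasured spill requiring $\epsilon > 0$ — and gives instances whose
correct answer is known by construction.

It does not emulate real metabolomics in several ways: unit stoichiometry
(no cofactor coupling, no biomass-style lumped reactions), no measurement
bias (intervals always contain the truth), no compartments, and
desk-scale size. Passing the planted-recovery and oracle-equivalence tests
therefore certifies the optimisation machinery, not the biological fidelity
of predictions on genome-scale models, which depend on measured coverage
and on the model's quality.

Problem sizes used by the test-suite and the acceptance script: 50 random
planted instances with at most 12 split reactions (the exhaustive oracle
enumerates every support, so it is size-guarded at 14), plus all
chain/branch/cycle topologies of 3–10 metabolites. These sizes keep the
dual-route certification (solver vs. exhaustive enumeration) exact and
fast; they are a validation design choice, not a limit of the solver, which
accepts any instance and scales with the usual mixed-integer cost.

## Known limitations

* The bundled branch-and-bound targets desk-scale certification; genome-scale
  models (thousands of reactions) need an industrial MILP solver behind the
  same problem abstraction. The model I/O and problem assembly already
  handle BiGG-style networks.
* The moles-passed vector is an integral, not a trajectory: no kinetics, no
  ordering of events within the transient, no time-course fitting.
* Predictions exist only where measurements constrain the network: regions
  far from any measured metabolite legitimately come back empty.
* No gene–protein–reaction logic, no unit conversion (the user supplies
  concentration × volume in consistent mole units), and no statistical
  significance testing of the input changes — intervals are taken as given.
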