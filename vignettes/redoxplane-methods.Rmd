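---
title: "Methods: shadow-price analysis of reducing-capacity availability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shadow-price analysis of reducing-capacity availability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redoxplane)
```

## The model and its assumptions

Every computation in this package runs on a flux balance analysis (FBA)
problem: maximise a single biomass flux $Z$ over flux vectors $v$ satisfying
steady-state mass balance $S v = 0$ and bounds $lb \le v \le ub$, with the
BiGG sign convention that negative exchange flux is uptake. The assumptions
are the standard ones of constraint-based modelling: a pseudo-steady state
for internal metabolites, growth-optimal regulation, and bounds in
mmol·gDW⁻¹·h⁻¹ as the only kinetic information (the biomass column is scaled
so $Z$ carries h⁻¹). A bound magnitude of 1000 stands in for "unbounded" —
large enough never to bind in any regime analysed here.

The scientific object of interest is the metabolite shadow price: the dual
variable $\gamma_i$ of metabolite $i$'s balance row, equal to
$\partial Z^*/\partial b_i$ where $b_i$ relaxes $S_i v = 0$ towards an
external supply. With the sign convention used throughout, $\gamma_i < 0$
means a small supply of $i$ would raise optimal growth ($i$ is
growth-limiting) and $\gamma_i > 0$ means $i$ is available in excess. The
composite price

$$\gamma_{red} = \gamma_{NADH} - \gamma_{NAD}$$

is the sensitivity of growth to a net external reduction NAD → NADH, i.e. to
the availability of reducing capacity. It is antisymmetric in the two
cofactors by construction. A phenotype is classified *limiting* when
$\gamma_{red} < -10^{-6}$, *excess* when $\gamma_{red} > 10^{-6}$, and
*neutral* otherwise; the $10^{-6}$ guard simply absorbs solver tolerance on
a quantity whose natural magnitude in these models is $10^{-2}$–$10^{-1}$.

### Which cofactor pool?

Compartmentalised models carry several NADH/NAD pairs. All high-level
functions take a `compartment` argument, defaulting to the cytosolic pair
(`"c"`), because the cytosolic redox state is what the
glycolysis/fermentation branch point sees; `gamma_red_table()` reports every
compartment so the choice is auditable.

## The LP engine and its duals

No linear-programming package with dual extraction is available to this
package's dependency set, so `redoxplane` carries its own bounded-variable
two-phase primal simplex (`R/lp.R`): dense, refactorised at every pivot,
Bland's rule throughout (guaranteed termination), feasibility and optimality
tolerances of $10^{-9}$, single-threaded and fully deterministic. The solver
configuration is embedded in every fit object. This design favours
transparency and exact reproducibility over speed; it is comfortable for
models up to a few hundred reactions. For genome-scale matrices
(thousands of reactions) solves complete but are slow — see *Limitations*.

Each optimal solve is audited in place: $\|S v\|_\infty \le 10^{-6}$ and the
strong-duality gap between $c'v$ and the bound-multiplier dual objective
must close to $10^{-6}$, otherwise the fit aborts rather than returning
questionable duals.

### Degenerate duals

At phase boundaries the optimal dual vector is not unique, and any single
returned $\gamma$ is an arbitrary selection. Two mechanisms guard against
misclassification:

* a cheap screen inside `fba()`: re-solving under a deterministic $10^{-7}$
  bound jitter and a $10^{-7}$ cost jitter, flagging metabolites whose dual
  moves by more than $10^{-4}$;
* an exact certificate on demand (`shadow_price`, `gamma_red`,
  `verify_fd`): the range of the queried dual weight over the full optimal
  dual polytope, cut out by complementary slackness at the solved vertex, is
  computed with two further small LPs. The jitter screen alone can miss
  degeneracy when the same degenerate basis survives the perturbation — the
  exact range cannot.

Wherever a queried price is degenerate, classification falls back to a
finite-difference probe: a temporary reaction supplying the metabolite (or,
for $\gamma_{red}$, converting NAD to NADH) at a fixed flux of $10^{-3}$
mmol·gDW⁻¹·h⁻¹, the difference quotient of the two optima. The probe
magnitude balances staying within one LP basis against numerical noise and
is configurable. `verify_fd()` exposes the same probe as a user-facing
check; agreement is defined as $|fd - \gamma| \le \max(10^{-6},
0.01|\gamma|)$.

### Cycle removal

Stoichiometrically balanced cycles can inflate internal fluxes without
affecting any exchange or the objective. `remove_loops()` post-processes an
optimal solution by minimising total absolute internal flux with all
exchange fluxes and the objective pinned — an L1 clean-up in the spirit of
CycleFreeFlux. Because a mixed-integer loop-law formulation has no duals,
while every shadow price in this package requires LP duality, loop handling
is deliberately kept as a post-process: it provably cannot change the
objective or any exchange flux, so all reported quantities are unaffected,
and duals are always taken from the plain LP. Loopless flux variability
(each extreme re-cleaned under its own pin) is available as an option and
can only tighten spans.

## Phase planes, the line of optimality, and patterns

`phpp_scan()` evaluates the FBA optimum on a glucose × oxygen grid of
maximal uptakes (defaults: 20 × 20 over [0, 10] × [0, 14] for the toys;
resolution and ranges are configurable and a 40 × 40 grid is the suggested
setting for genome-scale models). The line of optimality — the uptake ratio
of maximal biomass yield, i.e. fully respiratory metabolism — is computed
per glucose value as the *minimal* oxygen uptake attaining the
unbounded-oxygen optimum. The minimum matters: at the optimum the oxygen
flux itself can be degenerate (oxygen-wasting alternate optima exist
wherever a non-phosphorylating oxidase is present), so "the oxygen uptake at
the optimum" is only well-defined as the least such uptake, which is exactly
the maximal-yield ratio. Zero-growth feasible points are treated as
infeasible for pattern purposes, since a growth sensitivity is meaningless
at $Z = 0$.

A grid point is *oxygen-limited* when its oxygen bound lies strictly below
the line of optimality at its glucose value; points within one grid step of
the line are excluded from pattern statistics because the line is precisely
the degenerate locus. `availability_pattern()` summarises the feasible
oxygen-limited points: the fraction classified excess, with
`all_excess_o2_limited` (fraction = 1) the operational definition of the
Crabtree-positive pattern and `subset_excess` (0 < fraction < 1) the
Crabtree-negative one.

## Envelopes, spans and screens

`production_envelope()` fixes growth on an even grid from 0 to $Z^*$ (20
points by default, matching visual smoothness at low LP cost) and
min/maximises the product flux; growth is pinned with a two-sided $10^{-9}$
band rather than an inequality so the minimum at $Z^*$ is well-defined.
*Coupled* means the minimal product flux at maximal growth exceeds
$10^{-6}$: growth forces production.

`fva()` fixes growth at 100 % of the optimum (configurable) and min/maximises
every reaction. Spans $v_{max} - v_{min}$ are binned S1 (> 10),
S2 ((1, 10]), S3 ([0.01, 1]); spans below 0.01 are excluded so only
substantial flexibility is tallied. The closed/open boundary assignment is
this package's stated convention. `span_profile()` repeats the FVA across
oxygen bounds at fixed glucose uptake (default: 8 even values from 0.5 up to
the line-of-optimality oxygen) and reports an invariance metric — the
maximum over bins of the relative change in count — computed over the
strictly oxygen-limited entries only: in small networks all flexibility
trivially collapses *on* the line, so including the line point would erase
the distinction the metric exists to measure. The line entry is still
reported.

The deletion module works at reaction level (no gene–protein–reaction
logic): presets for the complex-I/alternative-oxidase double deletion and
the cytochrome-oxidase deletion resolved through a user-suppliable id map;
an exhaustive single-deletion screen with a coarse 8 × 8 grid and 20 × 20
confirmation (two-stage screening bounds the LP count, and exchanges, the
biomass column and zero-span reactions are pruned from candidates since such
deletions cannot change the optimum pattern); and a growth-coupled design
search that runs exhaustive single-deletion scoring first and then a
deterministic beam search (width 5, add/swap moves, lexicographic
tie-breaks) over sets of up to three deletions, iterated over a ladder of
minimal-growth constraints (0.1–0.7 h⁻¹ by 0.1). On the bundled toys the
search is verified to return exactly the exhaustively enumerated coupled
sets; the bounded search exists so the same interface scales to models where
enumeration is not an option.

The NADH-sink modified model adds an irreversible pure NADH drain (bounds
0.1–0.6 mmol·gDW⁻¹·h⁻¹, minimal growth 0.20 h⁻¹ by default) — deliberately
*not* an NADH → NAD oxidase, since the point is to remove reducing
equivalents, not to regenerate the oxidised pool. In a model whose NAD(H)
pool is strictly closed (as in the bundled toys, where every reaction
conserves NADH + NAD) a pure drain is stoichiometrically infeasible, so the
variant detects closure and adds an explicit NAD-salvage inflow alongside
the drain; genome-scale models keep the pool open through biosynthesis and
need no salvage.

## The synthetic toy models

`toy_cerevisiae()` (TOY-SC) and `toy_stipitis()` (TOY-SS) are deterministic
generators for two small stoichiometric networks (13 and 15 reactions) with
explicit NADH/NAD — and, in TOY-SS, NADPH/NADP — bookkeeping. They emulate
the qualitative physiology that distinguishes an overflow-metabolising yeast
from a redox-recycling pentose fermenter:

* **TOY-SC**: lumped glycolysis (glc + 2 NAD → 2 pyr + 2 NADH + 2 ATP),
  lumped TCA (pyr + 4 NAD → 4 NADH + 1 ATP + 3 CO₂), a respiratory chain
  with P/O 1.5, fermentation to ethanol through one major and several
  capacity-staggered minor isozymes (caps 0.5, 2 and 12 mmol·gDW⁻¹·h⁻¹,
  standing for the organism's redundant PDC/ADH complement), and a biomass
  reaction drawing 12 pyruvate, 40 ATP and 4 NADH per unit growth, plus a
  fixed maintenance demand of 1 mmol ATP·gDW⁻¹·h⁻¹.
* **TOY-SS**: the same backbone plus the known NADH-recycling routes — a
  capacity-capped alternative oxidase (no ATP), an NADH → NADPH
  transhydrogenase-like bypass, a low-capacity polyol sink (2 NADH per
  pyruvate) and a cyclic oxidative-PPP NADPH source — with biomass drawing
  NADPH (16 pyruvate, 35 ATP, 5 NADPH) and its lumped TCA booking no net
  substrate-level ATP.

All coefficients are frozen calibration constants, tuned once against the
finite-difference oracle until four qualitative contrasts held, and not
revisited: (i) ethanol production is growth-coupled in TOY-SC under a
binding oxygen bound and non-coupled in TOY-SS aerobically; (ii) TOY-SC
shows excess reducing capacity at *every* oxygen-limited phenotype while
TOY-SS shows it only in a low-oxygen sub-region, with a limiting band
hugging its line of optimality; (iii) TOY-SC's span bins swing across the
oxygen-limited range while TOY-SS's stay nearly constant; (iv) deleting
TOY-SS's recycling routes (AOX, THD, POLYOL) flips its availability pattern
to the all-excess one.

Two calibration choices deserve explanation because LP duality makes them
structural rather than cosmetic. First, whenever the lumped TCA reaction is
active in the network interior, complementary slackness pins
$4\,\gamma_{red} = \gamma_{pyr} - a\,\gamma_{ATP}$, where $a$ is TCA's
substrate-level ATP yield. With $a = 1$ (TOY-SC) an ATP-valuable economy
forces the excess classification left of the line; with $a = 0$ (TOY-SS,
whose lumped turn books the GTP into maintenance) the same identity makes
$\gamma_{red}$ strictly negative wherever TCA runs to feed the
transhydrogenase bypass — which is exactly the limiting band near the line,
and which disappears when the bypass is deleted. Second, the fermentative
isozyme caps are what let TOY-SC's flux spans grow with oxygen limitation:
the redundant isozymes split a disposal flux that only exists when overflow
is active, so alternate optima appear exactly where the overflow phenotype
does, while TOY-SS's single-copy routes with distinct marginal costs keep
its optima essentially unique (its only standing flexibility is the small
constant dial opened by the capped alternative oxidase).

### What the toys do and do not show

The toys reproduce availability *patterns*, coupling verdicts and span
*contrasts* — the qualitative, sign- and shape-level behaviour of the two
metabolic strategies. They do not attempt quantitative resemblance to
genome-scale yeast models: growth rates, yields and the line-of-optimality
slope are not calibrated to data; xylose metabolism, compartmentalisation,
gene-level redundancy and the hundreds of parallel pathways that give real
networks their flux-span counts are absent. Two concrete caveats follow.
Ethanol secretion begins strictly left of the line in TOY-SC, but in TOY-SS
a thin near-line band secretes nothing (the polyol sink and the bypass
absorb small surpluses first) — in that band the toys' geometry is cruder
than a genome-scale model's. And with its recycling routes deleted, TOY-SS
retains no route that can dissipate surplus ATP, so the deletant's growth
plateaus and its line of optimality sits at low oxygen almost independently
of glucose; the pattern flip is unaffected, but the deletant's absolute
growth values should not be over-interpreted. Passing the toy suite
therefore validates the *machinery* (duals, probes, grids, screens) and the
patterns' internal consistency, not any quantitative statement about real
yeast.

## Numerical choices, in one place

| Quantity | Value | Where |
|---|---|---|
| Solver feasibility / optimality tolerance | $10^{-9}$ | `lp.R` |
| Steady-state audit | $\|S v\|_\infty \le 10^{-6}$ | `fba()` |
| Strong-duality audit | gap $\le 10^{-6}$ (relative) | `fba()` |
| Degeneracy jitter / threshold | $10^{-7}$ / $10^{-4}$ | `fba()` |
| Classification guard $\varepsilon$ | $10^{-6}$ | `gamma_red()` |
| Finite-difference probe | $10^{-3}$ mmol·gDW⁻¹·h⁻¹ | `verify_fd()` |
| Growth pin for envelopes / FVA | $\pm 10^{-9}$ | `production_envelope()`, `fva()` |
| Coupling threshold | min product $> 10^{-6}$ | `coupling()` |
| Span bins | S1 > 10, S2 (1,10], S3 [0.01,1] | `fva()` |
| Zero-growth cut-off | $Z \le 10^{-8}$ treated as infeasible | `phpp_scan()` |
| Default bound magnitude | 1000 mmol·gDW⁻¹·h⁻¹ | model I/O |

Problem sizes were chosen to keep the full test suite and the acceptance
script comfortably interactive: 12–20-point grids for phase planes, 8-point
span profiles, 5 uptake settings for the finite-difference sweeps, and
exhaustive enumeration limited to the ≤ 3-deletion subsets of the toy
models (a few hundred LPs).

## Limitations

* The pure-R dense simplex is the right tool for the bundled models and for
  medium-sized networks; genome-scale matrices solve correctly but slowly,
  and the genome-scale acceptance checks in `tests/testthat/test-acceptance.R`
  additionally require model files that are not redistributed with the
  package.
* Shadow prices are LP duals: they are exact only for marginal
  perturbations, non-unique at phase boundaries (handled by the degeneracy
  machinery), and silent about kinetics and regulation.
* Loop handling is a post-process, not a mixed-integer loop law; this is a
  deliberate trade (see *Cycle removal*) but means internal flux values
  inside unremovable cycles pinned by bounds are not thermodynamically
  certified.
* Deletions are reaction-level; mapping to genes requires
  gene–protein–reaction logic outside this package's scope.
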