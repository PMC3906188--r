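# redoxplane

Constraint-based analysis of NAD(H/⁺) availability in yeast metabolism.

Crabtree-positive yeasts such as *Saccharomyces cerevisiae* ferment glucose to
ethanol even when oxygen is available, while Crabtree-negative pentose
fermenters such as *Scheffersomyces stipitis* only ferment when oxygen runs
short. `redoxplane` implements a genome-scale, duality-based way of telling
these metabolic strategies apart: it asks how optimal growth would respond to
a marginal injection of reducing equivalents, everywhere on the plane of
glucose and oxygen uptake rates, and what that implies for ethanol production
and network flexibility. The package is aimed at systems biologists working
with stoichiometric (COBRA-style) yeast models.

## The quantity at the core

Flux balance analysis (FBA) finds a flux vector `v` maximising the biomass
flux `Z` subject to steady state and bounds:

    max Z = c'v   s.t.   S v = 0,   lb ≤ v ≤ ub

The dual variable (shadow price) `γ_i` of metabolite *i*'s mass-balance row
measures the sensitivity of `Z` to a small relaxation `b_i` of that balance —
operationally, to a small external supply flux of *i*. Signs follow the
convention `γ_i < 0` ⇔ supply of *i* raises growth (*i* is growth-limiting),
`γ_i > 0` ⇔ *i* is in excess. The **available reducing capacity** is the
composite price

    γ_red = γ_NADH − γ_NAD

the growth sensitivity to a net external reduction NAD → NADH. `γ_red < 0`
means reducing capacity is limiting for biomass production; `γ_red > 0` means
it is in excess, and overflow routes (fermentation, polyols) are expected to
carry the surplus. Every dual the package reports is checked against an
independent finite-difference probe (`verify_fd`), and duals that are
non-unique at the optimum (phase boundaries) are flagged and re-evaluated by
probing.

Around this core the package provides phenotypic phase planes with the line
of optimality, ethanol–biomass production envelopes with growth-coupling
verdicts, flux variability analysis with span binning (S1 > 10,
1 < S2 ≤ 10, 0.01 ≤ S3 ≤ 1 mmol·gDW⁻¹·h⁻¹), reaction-deletion screens (a
priori respiratory presets, exhaustive pattern replication, a bounded local
search for growth-coupled designs, an NADH-sink modified-model procedure),
SBML (L3 FBC, legacy L2) and BiGG-JSON model I/O, and two small calibrated
toy yeast models (`toy_cerevisiae()`, `toy_stipitis()`) that reproduce the
qualitative contrasts between the two metabolic strategies without any
external model files.

## Worked example

```r
library(redoxplane)

sc <- toy_cerevisiae()
sc
#> Metabolic model: TOY-SC
#>   metabolites: 8  reactions: 13  exchanges: 4
#>   objective: BIOMASS

line_of_optimality(sc, 10)
#>   glc   o2   growth
#> 1  10 12.2 1.453846

m <- set_uptake(set_uptake(sc, "EX_glc", 10), "EX_o2", 4)  # oxygen-limited
fit <- fba(m)
fit
#> FBA fit (TOY-SC): status optimal, objective 0.783654 h^-1

gamma_red(fit, "c")
#> $gamma_red       0.00481
#> $classification  "excess"
```

At glucose uptake 10 and oxygen capped at 4 mmol·gDW⁻¹·h⁻¹ — well left of
the line of optimality at O₂ = 12.2 — growth drops from 1.45 to 0.78 h⁻¹ and
γ_red turns positive: reducing capacity is in excess, the signature of a
phenotype that must overflow. The envelope confirms growth-coupled ethanol:

```r
production_envelope(m, "EX_etoh")
#> Production envelope (TOY-SC): EX_etoh vs growth
#>   max growth 0.783654 h^-1; product at max growth in [10.25, 10.25]
#>   verdict: coupled
```

The Crabtree-negative toy shows the contrasting pattern — excess only in a
low-oxygen sub-region of the oxygen-limited phenotypes:

```r
grid <- phpp_scan(toy_stipitis(), steps = 12)
str(availability_pattern(grid))
#> $ fraction_excess      : num 0.824
#> $ all_excess_o2_limited: logi FALSE
#> $ subset_excess        : logi TRUE
```

A shell front-end for the same stages ships in `inst/scripts/redoxplane`:

```sh
Rscript inst/scripts/redoxplane phpp --model toy:ss --steps 20 --out results/
```

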