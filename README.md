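# egrowth — elementary growth modes and vectors for self-fabricating metabolic models

Traditional genome-scale metabolic models close their mass balance with a
*biomass reaction*: a fixed recipe of precursor consumption that every
prediction silently depends on.  Next-generation (resource-allocation-style)
models drop that recipe and make the cell fabricate itself — importers,
enzymes and the ribosome are explicit species, synthesized by the ribosome
out of amino acids — so biomass composition becomes a *result*.  `egrowth`
is for modellers who want the unbiased view of such models: the complete,
finite set of "functional units" that generate every feasible flux
distribution and every feasible biomass composition.

## The objects it computes

At balanced growth with rate μ (per hour), concentrations x (mol/g dry
weight) and fluxes v (mol/g/h) satisfy `N v = μ x ≥ 0` and the dry-mass
constraint `ωᵀx = 1`, hence `μ = ωᵀN v`.

* **Growth cone** `C_g = {v : Nv ≥ 0, v_I ≥ 0}` — stoichiometry and
  irreversibility only.  Its **elementary growth modes (EGMs)** are the
  conformally non-decomposable elements: the unique minimal set of
  generators such that every growth mode is a sum of sign-compatible EGMs
  (no cancellations).  Unlike classical elementary flux modes, EGMs are
  not support-minimal in general.
* **Growth polyhedron**
  `P_g(μ) = {v : Nv ≥ 0, v_I ≥ 0, ωᵀNv = μ, (AN + μB)v ≥ μb}` — adds
  linear capacity/membrane constraints `Ax + Bv ≥ b` at fixed growth rate.
  Its **elementary growth vectors (EGVs)** are the convex-conformally
  non-decomposable points plus the recession-cone generators; each EGV is
  characterized by its *inactive-constraint signature* (the inequality
  rows it satisfies strictly).
* **Conformal decompositions** of any growth mode/vector into these
  generators, with the exact concentration mixing identity
  `x(v) = Σ λ_e x(e)`.
* **Autocatalysis**: basically catalytic / catalytically closed /
  autocatalytic flags, kinetic consistency, and minimal autocatalytic
  (MAC) reaction sets via exact strict-feasibility LPs.

Everything is enumerated in **exact rational arithmetic** (double
description over arbitrary-precision integers): counts, signatures and
zero/nonzero decisions are exact, never tolerance calls.

## Worked example: the self-fabricating cell

The built-in case study has 11 species (glucose G, ammonium N, amino acids
AA, lipid droplets LD, membrane lipids L, two importers, three enzymes,
ribosome R) and 11 irreversible catalytic reactions.

```r
library(egrowth)
model <- self_fabricating_cell()
model
#> Growth model: 11 species, 11 reactions
#>   irreversible: 11  exchange: 2  catalytic: 11

egms(model)        # 11 EGMs, one per species, none with zero growth rate
ev <- egvs(model, mu = 0.5)
ev
#> Elementary growth vectors at mu = 0.5 /h
#>   24 point EGV(s), 0 recession-cone EGV(s)
#>           signature support gamma_IG gamma_IN    s_C w_R.x_R
#> 1     mb N | memb L      11   0.1202   0.8798 0.1035  0.0072
#> 2     mb N | cap IN      11   0.1473   0.8527 0.0570  0.0390
#> ...
#> 23   mb LD | memb L      11   0.9998   0.0002 0.9978  0.0009
#> 24    mb G | memb L      11   0.9998   0.0002 0.9979  0.0008
```

Reading the columns: every EGV has full support (all 11 reactions active)
and exactly two inactive constraints — its signature.  `gamma_IN` is the
ammonium contribution to growth (`ω_N v_IN / μ`; balanced uptake is
18/198 ≈ 0.091), `s_C` the carbon storage mass fraction (glucose + lipid),
`w_R.x_R` the ribosome mass fraction.  The first rows are
nitrogen-accumulating EGVs (γ_IN ≈ 0.85–0.88), the last rows carbon-storing
ones (s_C ≈ 1, γ_IN ≈ 0); low nitrogen uptake and high carbon storage come
as a package, with no regulation in the model.

Sweeping growth rate tracks EGV families by signature and locates the
regime boundaries by bisection:

```r
sw <- sweep_mu(model)
sw
#> Growth-rate sweep on [ 0.05 , 1.5 ] /h
#>   point-EGV counts over feasible grid: 24 -> 10
#>   mu_crit (EGV count changes): 1.2122 /h
#>   mu_max (feasibility boundary): 1.2643 /h
#>   families (distinct inactive signatures): 26
table(sw$classes$uptake_class)
#> 1a 1b 2a 2b 3a 3b
#>  2  4  1  2  5 12
```

Autocatalysis of the bare stoichiometry versus the constrained model:

```r
mac_sets(model)    # exactly one MAC set: the lipid-free self-fabricating core
#> [[1]]
#> [1] "r_EAA" "r_IG"  "r_IN"  "s_EAA" "s_IG"  "s_IN"  "s_R"
classify_gm(model, ev$flux[1, ])$autocatalytic   # every EGV is AC
#> [1] TRUE
```

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/egrowth.R egm   --model inst/extdata/self_fabricating_cell.json --out out/
Rscript inst/cli/egrowth.R sweep --model inst/extdata/self_fabricating_cell.json --out out/
```

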