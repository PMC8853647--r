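---
title: "Elementary growth modes and vectors: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elementary growth modes and vectors: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egrowth)
```

## The modelling problem

Traditional constraint-based metabolic models close the mass balance with a
*biomass reaction*: a single column that consumes precursor metabolites in
fixed proportions.  Everything such a model predicts is conditional on that
composition, which is uncertain and varies across conditions.
Next-generation (self-fabricating) models remove the biomass reaction and
make macromolecule synthesis explicit: importers, enzymes and the ribosome
are species, and the ribosome synthesizes all of them, including itself.
Biomass composition then stops being an input.  At balanced exponential
growth with rate $\mu$, concentrations $x$ (mol per gram dry weight) and
fluxes $v$ (mol/g/h) satisfy

$$Nv = \mu x, \qquad \omega^T x = 1,$$

with stoichiometric matrix $N$ and molar masses $\omega$.  Consequently
$\mu = \omega^T N v$, and because internal reactions conserve mass
($\omega^T N_{int} = 0$), growth rate is paid for entirely by exchange
fluxes.  Two structural assumptions are validated for every model
(`validate_model()`): exact internal mass conservation, and absence of
semipositive conservation laws ($\ker N^T \cap \mathbb{R}^{Mol}_{\ge 0} =
\{0\}$, decided by an exact feasibility LP) — a conserved nonnegative pool
cannot grow exponentially.

## Growth cone, growth polyhedron, and their elementary vectors

Dropping everything except stoichiometry and irreversibility leaves the
*growth cone* $C_g = \{v : Nv \ge 0,\ v_I \ge 0\}$, a general polyhedral
cone (the flux cone $\{Nv = 0\}$ of traditional analysis is the special
case lying in a subspace).  Its unique minimal conformal generating set —
decompositions without cancellation, $\mathrm{sign}(e) \le
\mathrm{sign}(v)$ — consists of the conformally non-decomposable (cND)
vectors, the **elementary growth modes** (EGMs).  EGMs are generally *not*
support-minimal; support minimality characterizes elementary vectors only
in s-cones.

Adding linear capacity constraints $Ax + Bv \ge b$ and fixing $\mu$ (the
problem is nonlinear in $\mu$ otherwise) and eliminating $x = Nv/\mu$
yields the *growth polyhedron*

$$P_g(\mu) = \{v : Nv \ge 0,\ v_I \ge 0,\ \omega^T N v = \mu,\
  (AN + \mu B)v \ge \mu b\}.$$

Its conformal generators — the **elementary growth vectors** (EGVs) — are
the convex-conformally non-decomposable (ccND) points plus the cND rays of
the recession cone.  EGVs are characterized not by supports but by their
*inactive-constraint signatures*: the set of inequality rows satisfied
strictly.

## Exact enumeration

All enumeration runs over exact rational arithmetic ("p/q" strings at the R
boundary, arbitrary-precision integers in compiled code), because counts and
signatures are yes/no questions that floating point gets wrong near
degeneracy.  The pipeline reduces every case to one primitive — extreme rays
of $\{z \ge 0, Mz = 0\}$ by double description with combinatorial adjacency
— via the classical correspondence between conformal non-decomposability
and support minimality:

* general cone $\{Ax \ge 0\}$: split free coordinates ($x = x^+ - x^-$),
  add one slack per inequality row, enumerate support-minimal vectors of
  the lift, drop artifacts with $x^+ \circ x^- \ne 0$, map back;
* polyhedron: homogenize with a variable $t \ge 0$
  ($\{(x,t): Ax - bt \ge 0\}$); rays with $t > 0$ rescale to the ccND
  points, rays with $t = 0$ are the recession-cone EVs.  No ray with
  $t > 0$ means the polyhedron is infeasible — reported as a first-class
  result because the feasibility boundary in $\mu$ is located by bisection
  on exactly this outcome;
* equality rows stay equalities in the backend (splitting them into
  inequality pairs would duplicate active-set signatures); rows that are
  positive multiples of an irreversibility bound, or exact duplicates of an
  earlier row, are merged before enumeration and excluded from signatures.
  This is why a signature such as "two inactive constraints per EGV" refers
  to the *essential* rows: metabolite mass balances, capacity rows and the
  membrane inequality, not the trivially slack single-coordinate rows.

cND/ccND membership is also available as a direct test (`is_cnd()`,
`is_ccnd()`): sign-compatible decompositions of $v$ live on the minimal
face of the cone through $v$ intersected with $v$'s closed orthant, so
$v$ is cND iff $\{A_{act}x = 0,\ x_{supp^c(v)} = 0\}$ has nullity one
(ccND: the affine analogue has nullity zero).  This rank characterization
is equivalent to the LP formulation over the face and is exact.

Conformal decomposition (`conformal_decompose()`) follows the constructive
proof of the generating theorems: greedily subtract the largest
sign-compatible multiple of an EV that keeps the remainder in the set; each
step zeroes a coordinate of $x$ or $Ax$, bounding the number of terms by
$|supp(x)| + |supp(Ax)|$ (+1 for polyhedra, where the homogenized $t$
coordinate makes the point coefficients sum to one automatically).  The
decomposition is exact — the reconstruction residual is identically zero —
but not unique in general; coefficients are only recovered uniquely when
the participating EVs are linearly independent (as for the 11 EGMs of the
case-study model, whose $N$ is invertible).

A float mode (`arithmetic = "float"`, tolerance $10^{-9}$) exists for
larger models; it trades exact signatures for speed and is not used in any
result reported here.  Genome-scale enumeration is out of scope — the
number of elementary vectors explodes combinatorially.

## The self-fabricating cell and its constraints

`self_fabricating_cell()` builds the 11-species, 11-reaction case study:
glucose (G, 180 g/mol) and ammonium (N, 18 g/mol) import, amino-acid
synthesis (G + N → AA), lipid-droplet formation (7 G → LD), membrane-lipid
transfer (LD → L), and ribosomal synthesis of the five catalytic proteins
(646 AA per importer, 325 per enzyme) and the ribosome itself (22608 AA,
RNA content folded in).  All other masses follow from
$\omega^T N_{int} = 0$ (`derive_masses()`), e.g. $\omega_{AA} = 198$,
$\omega_R = 22608 \times 198$ g/mol.  The stoichiometric matrix is square
and invertible, which is why there are exactly 11 EGMs, each producing
exactly one species, and no elementary flux modes (no EGM with $\mu = 0$).

The constraint set (`capacity_constraints()`) uses canonical units h, mol,
g, m:

| constraint | form | parameters |
|---|---|---|
| catalytic capacity (5 rows) | $v_r \le k_{cat} x_{cat(r)}$ | $k_{cat} = 79 \cdot 3600$ /h |
| ribosome capacity | $\sum_r n_r w_r \le k_{el} x_R$ | $k_{el} = 8 \cdot 3600$ AA/h |
| membrane area (equality) | $A_L x_L + A_I(x_{IG}+x_{IN}) = r(\mu)/(\rho N_A)$ | $A_L = 0.5$, $A_I = 48$ nm²; $\rho = 290$ g/L |
| minimum lipid fraction | $(1-\alpha)A_L x_L \ge \alpha A_I (x_{IG}+x_{IN})$ | $\alpha = 1/2$ |

with surface-to-volume ratio $r(\mu) = (9.3 - 2.8\,\mu\,\mathrm{h})\,
\mu\mathrm{m}^{-1}$ (the tabulated unit is ambiguous; only an inverse
length is dimensionally consistent with the area balance).  Internally the
membrane rows are scaled by the Avogadro constant — a positive row scaling
that changes neither the polyhedron nor any signature but keeps the
rational entries small.  With these conversions the model has two regimes:
24 EGVs up to $\mu_{crit} \approx 1.212$/h, 10 EGVs up to
$\mu_{max} \approx 1.264$/h, located by bisection to $10^{-4}$/h on the
EGV count and on feasibility respectively (default grid step 0.05/h).

## Classification conventions

Families (inactive signatures) are classified by uptake and by ribosome
content (`classify_egvs()`).  The uptake fraction of ammonium is
$\gamma_{IN} = \omega_N v_{IN}/\mu$, with balanced value
$\omega_N/(\omega_G + \omega_N) = 1/11 \approx 0.091$ at equal molar
uptake rates.  Classes: 1 below balanced (carbon storage), 2 above
(nitrogen accumulation), 3 balanced within 0.02; suffix a/b for families
valid at all growth rates versus confined to one regime.  Note that the
"balanced" families are mildly glucose-rich at low $\mu$ (membrane lipids
cost glucose but no nitrogen), dipping to $\gamma_{IN} \approx 0.079$ at
$\mu = 0.05$/h; the balanced value is approached as $\mu \to \mu_{max}$.
The asymmetric small-$\mu$ limits are a consequence of the membrane
equality: $\gamma_{IN} \to 0$ for glucose-rich families but
$\gamma_{IN} \to 0.87$ (not 1) for ammonium-rich ones.

Ribosome classes are qualitative descriptions made operational by
thresholds chosen inside the (wide) numerical gaps observed in the exact
sweep: class III = mass fraction $\omega_R x_R$ constant across the
family's validity interval (total variation $\le 0.05$; observed either
$\le 0.048$ or $\ge 0.87$), class II = affine through the origin (maximum
deviation from the best through-origin line $\le 0.02$; observed either
$\le 0.011$ or $\ge 0.40$), class I = the rest.  Constancy is tested before
linearity because a constant on a narrow interval also fits a line.  The
constant class sits at $\omega_R x_R \approx 0.9$: these are the families
with slack ribosome capacity (or slack importer capacity in regime H),
where the excess dry mass is ribosomal.  With the unit conversions above,
the classes come out as 12 storage-type families (nonlinear), 9
linear-through-origin, and 5 constant-high — the storage families'
ribosome content necessarily vanishes as $\mu \to 0$, since stored
glucose/lipid/ammonium then dominates the dry mass.

Two more fine points of the exact sweep.  Carbon storage
$s_C = \omega_G x_G + \omega_{LD} x_{LD} + \omega_L x_L$ decreases with
growth rate throughout the low regime, but *includes membrane lipid*: near
$\mu_{max}$, importers crowd the membrane and the minimum-lipid-fraction
constraint forces extra lipid, producing a small uptick for the regime-H
and nitrogen-storage families.  And the 10 regime-H EGVs merge into a
single flux vector only in the limit $\mu \to \mu_{max}$; the flux spread
across them contracts monotonically but is still visible at
$\mu_{max} - 5\times 10^{-4}$.

## Autocatalysis and kinetic consistency

With explicit catalysts, autocatalysis is decidable from $Nv$ alone:
basically catalytic (some active catalytic reaction), catalytically closed
(every active catalyst produced, $(Nv)_s > 0$), autocatalytic = both.
Kinetic consistency asks more: every species *touched* by an active
reaction must be produced.  MAC sets (inclusion-minimal supports of
autocatalytic modes) are found by walking the union lattice of EGM supports
(every growth-mode support is such a union, by conformal decomposition)
with an exact strict-feasibility LP per candidate — strictness is
LP-decidable thanks to a normalization row $\sum v = 1$.  The search
requires irreversible candidate supports; for reversible reactions the
sign pattern of a support is not a convex condition, and no model in this
package needs it.  For the case-study model the only MAC set is the
lipid-free core (both importers, amino-acid synthesis, their expression,
and ribosome synthesis); under the capacity constraints every EGV has full
support, hence every EGV is autocatalytic and the full reaction set is the
only autocatalytic support realized — yet no EGV is kinetically
consistent, since at most one of the four metabolites has nonzero
associated concentration.

## The traditional-model comparison

`traditional_model()` rebuilds the classical counterpart: metabolite rows
only, enzymatic reactions, plus one biomass column consuming the
precursors in proportion to a reference composition (taken from a
maximum-growth EGV), with macromolecules folded into their total
amino-acid content $x_{AA}^{tot} = n_I(x_{IG}+x_{IN}) +
n_E(x_{EAA}+x_{ELD}+x_{EL}) + n_R x_R + x_{AA}$.  The column is scaled by
the total precursor concentration $\bar x$ (their molar sum) to be
dimensionless; one unit of biomass flux then consumes exactly one gram of
precursors per gram dry weight, because the reference state satisfies
$\omega^T x = 1$.  The resulting flux cone has a single elementary flux
mode, and with capacity bounds frozen at the reference enzyme
concentrations the flux polyhedron has a single nonzero elementary flux
vector (the zero flux vector, a feasible vertex, is not counted as a
phenotype): the traditional model is feasible but uninformative, in
contrast to the 11 EGMs and 24/10 EGVs of the comprehensive model.

## Synthetic models for property tests

`random_growth_model()` generates mass-consistent random models: random
metabolite masses, one exchange import per metabolite, internal reactions
whose last stoichiometric coefficient is solved from mass balance,
macromolecule synthesis under a ribosome-like catalyst, and rejection of
the (rare) draws with semipositive conservation laws.  These models
emulate the *structural* properties real networks must have (exact mass
balance, no conservation laws, catalytic closure structure) but none of
the biology: no realistic mass spectrum, no membrane, no capacity
parameters.  Tests passing on them certify the polyhedral and validation
machinery, not biological realism.

## Numerical choices and limitations

* Growth rates given as R numerics are converted to nearby
  small-denominator fractions (`rationalize()`, tolerance $10^{-9}$,
  denominators up to $10^7$); exact strings like `"1/2"` bypass this.
  Bisection midpoints are computed in exact arithmetic.
* Canonical scaling: cone rays are reduced to coprime integer vectors
  (positive scaling only — flipping would leave the cone); an
  orientation convention (first nonzero entry positive) applies only to
  the sign-ambiguous $\pm$ pairs of s-cones, where both orientations are
  members.  Polyhedron points are reported at $t = 1$, unscaled.
* Problem sizes: all shipped analyses are desk-scale (polyhedra in
  $\mathbb{R}^{11}$, $\le$ 33 lifted variables).  The full growth-rate
  sweep (30 grid points plus two bisections to $10^{-4}$/h) runs in well
  under a minute; property tests use random cones of dimension $\le 5$
  where brute-force oracles are exhaustive.
* The membrane parameters fix $\mu_{max}$ at 1.264/h, slightly below the
  rounded 1.27/h obtained with the original constants; all counts,
  signatures, classes and limits are insensitive to this sub-percent
  difference.
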