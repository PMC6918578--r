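---
title: "Methods: thermodynamics, pathway comparison and sequence triage in methylopath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermodynamics, pathway comparison and sequence triage in methylopath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylopath)
```

# Scope

`methylopath` evaluates, entirely in silico, whether an oleaginous yeast
such as *Yarrowia lipolytica* could assimilate methanol through a synthetic
formaldehyde route. Three questions structure the package:

1. **Thermodynamics.** How much formaldehyde can the native, NAD-dependent
   alcohol-dehydrogenase reaction produce from methanol at equilibrium, as
   a function of temperature?
2. **Stoichiometry.** Once formaldehyde exists, which of three
   assimilation pathways — the ribulose monophosphate (RuMP) pathway, the
   xylulose monophosphate (XuMP) pathway, or the bacterial serine cycle —
   supports the highest growth or triacylglycerol (TAG) yield?
3. **Sequence triage.** Among candidate hexulose-6-phosphate synthase
   (HPS) proteins, how should a large retrieved set be reduced to a
   non-redundant panel and organised phylogenetically for selection?

# The thermodynamic model

## Formaldehyde is a pool, not a species

In water, formaldehyde hydrates almost completely to methylene glycol,
CH~2~(OH)~2~. Equilibrium measurements therefore see the *pool* of both
forms, and formation data compiled from the literature are mutually
inconsistent unless the pool is treated explicitly. The package models the
pool as a pseudo-species whose chemical potential is

$$\Delta_f G_\mathrm{pool}(T) = -RT \ln \sum_i e^{-\Delta_f G_i(T)/RT},$$

a soft minimum over the component formation energies, with the hydration
water held at unit activity ([`pool_formation_energy()`]). The dominant
component (methylene glycol, hydration constant of order 10^3^) carries
essentially all the weight; the uncertainty propagates through the same
weights, $\sigma_\mathrm{pool}^2 = \sum_i w_i^2 \sigma_i^2$.

## Reconciliation of literature records

Independent estimates of one property are combined by inverse-variance
weighting ([`reconcile()`]). When the records scatter more than their
stated uncertainties allow (reduced chi-square above one), the combined
standard error is inflated by the Birge ratio
$\sqrt{\chi^2/(n-1)}$ — the standard treatment for inconsistent
measurement series. The packaged compilation
(`pool_compilation_records()`) reconciles to the literature consensus for
the formaldehyde/methylene-glycol pool, 130.54 ± 3.3 kJ/mol at 298.15 K.

## Temperature extrapolation

Species Gibbs energies are extrapolated from the reference temperature
with the Gibbs–Helmholtz relation,

$$G(T) = H(T_0) + \int_{T_0}^{T} C_p\,dT
       - T\Big[S(T_0) + \int_{T_0}^{T} \tfrac{C_p}{T}\,dT\Big],$$

with the formation entropy derived as $(H - G)/T_0$ and $C_p$ a constant
or quadratic polynomial $a + bT + cT^2$; both integrals are evaluated in
closed form ([`delta_r_g()`]). With $C_p \equiv 0$ this reduces to the
van't Hoff behaviour — the slope of $\ln K$ against $1/T$ equals
$-\Delta_r H/R$ — which the test suite checks by finite differences.

## The ADH equilibrium and its conventions

The equilibrium pool concentration in a defined medium follows from
$K(T) = e^{-\Delta_r G(T)/RT}$ as
$[\mathrm{pool}] = K\,[\mathrm{MeOH}]\,[\mathrm{NAD}^+]/[\mathrm{NADH}]$
in the dilute-product approximation; a mass-balance mode solves the full
equilibrium polynomial by root finding and agrees with the approximation
whenever the product stays far below every reactant
([`adh_equilibrium_formaldehyde()`]).

Conventions and defaults, chosen once:

* **Standard state.** Transformed (pH-dependent) formation energies with
  water at unit activity; no ionic-strength corrections (no ionic strength
  is reported for the reference medium). The NAD couple anchors the
  convention with NAD^+^ at zero.
* **Cofactor ratio.** The reported equilibrium series (34, 40 and 170 µM
  of pool formaldehyde at 28, 30 and 50 °C in 0.5 M methanol) does not
  come with a printed NAD^+^/NADH ratio; the package fixes the ratio at 1
  and makes it an explicit entry of `medium_conditions()`, so any other
  assumption is one argument away.
* **Temperatures.** Kelvin internally; Celsius accepted at every interface
  via `celsius = TRUE` or `celsius_to_kelvin()`.
* **Reference data.** `reference_thermo_table()` is a *synthetic* reference
  table: it encodes the reconciled pool formation energy (130.54 ± 3.3
  kJ/mol) and reaction enthalpy/entropy values consistent with the
  published temperature series above, because the underlying raw
  compilation is not redistributable. It is the package's calibration
  anchor, not a primary data source.

# The constraint-based model

## FBA, FVA and the LP kernel

Flux balance analysis maximises an objective reaction subject to steady
state $S v = 0$ and flux bounds ([`fba()`]). Because optimal flux vectors
are generally non-unique, only objective values are compared between
pathways; per-reaction ranges at any fraction of the optimum are available
from [`fva()`]. The LP kernel is a dense two-phase simplex written for
this package (`lp_solve()`): Dantzig pivoting with a Bland-rule fallback
guarantees termination and a reproducible vertex. It is sized for reduced
models (tens of reactions) and deliberately favours transparency over
speed; the suite verifies it against vertex-enumeration and hand-derived
dual oracles. Feasibility of returned solutions is re-checked against
$\|S v\|_\infty < 10^{-6}$, with bounds honoured to 10^-9^.

## The bundled core model

`generate_core_model()` builds a single-compartment, ~40-reaction
yeast-like network: glycolysis/gluconeogenesis (with fructose
bisphosphatase), the oxidative and non-oxidative pentose phosphate pathway
(transketolase/transaldolase recycling), the TCA cycle, the glyoxylate
shunt with PEP carboxykinase (the oleaginous host grows on acetyl units),
oxidative phosphorylation with a configurable P/O ratio, exchanges for
glucose, glycerol, methanol, O~2~ and CO~2~ (CO~2~ secretion-only, so
carbon yields cannot exceed one), a 7-carbon lumped biomass equation and a
55-carbon TAG sink. The alcohol-dehydrogenase reaction interconverting
methanol and formaldehyde exists but is closed until a pathway extension
opens it, and no native formaldehyde consumer exists — methanol alone
supports zero growth by construction.

Parameter defaults, fixed at design time:

* **P/O ratio 1.5** — the usual effective value for yeast mitochondria.
* **Growth-associated ATP maintenance 10 mol/mol biomass** (on top of 3
  mol/mol of explicit precursor costs, ≈1.9 ATP per biomass carbon, the
  scale genome-scale yeast biomass equations carry once polymerisation is
  included). This makes energy a genuinely binding resource, which the
  pathway ranking depends on; maintenance is growth-associated rather than
  a fixed demand so that the model stays feasible (with zero objective)
  under starvation.
* **TAG carbon 55** — a glycerol backbone plus 26 acetyl units.

The network's analytic yields were fixed when it was designed: the optimal
basis for growth on glucose was identified once, and solving the
steady-state equations of that support (a square linear system — no
optimisation involved) gives exactly 66/113 biomass flux per mmol glucose.
That vertex certificate is a permanent oracle in the test suite.

## Pathway extensions

[`build_extension()`] writes each heterologous route carbon- and
cofactor-explicit, in the cytosol (matching the engineering aim of
co-localising methanol oxidation and formaldehyde assimilation):

* **RuMP**: HPS (formaldehyde + ribulose-5-phosphate → hexulose
  6-phosphate) and PHI (→ fructose-6-phosphate).
* **XuMP**: DHAS (formaldehyde + xylulose-5-phosphate → dihydroxyacetone +
  glyceraldehyde-3-phosphate) and dihydroxyacetone kinase.
* **Serine cycle**: THF loading of formaldehyde, serine
  hydroxymethyltransferase, serine–glyoxylate aminotransferase,
  hydroxypyruvate reductase, glycerate kinase, PEP carboxylase, malate
  dehydrogenase, malate thiokinase and malyl-CoA lyase — the canonical
  alpha-proteobacterial cycle. Each reaction id accepts a `doc_override`
  replacement so a curated reaction set can substitute the defaults.

The serine cycle's net product is acetyl-CoA; its contribution to growth
therefore depends on the host's glyoxylate shunt, which is why the shunt
belongs to the core network rather than the extension.

On the bundled model the growth ranking under identical methanol uptake is
RuMP > XuMP > serine cycle: RuMP assimilates three formaldehyde into a
triose with no ATP cost, XuMP pays one ATP per formaldehyde at the kinase
step, and the serine cycle pays two ATP plus two NADH per acetyl unit.
The ranking is an energetic statement — with unlimited oxygen and no
maintenance the three routes would hardly separate, and the serine cycle's
CO~2~ refixation at PEP carboxylase would even favour it on pure carbon
terms (visible in its higher TAG carbon yield, where no biomass-linked
maintenance applies).

## Units and reporting

Methanol is a one-carbon substrate, so its uptake flux is numerically its
carbon-molar rate; the default uptake is 6 (flux units of the model).
Yields are reported both per carbon mole (`carbon_yield`) and per mole
(`mol_yield`), and oxygen demand per cmol of methanol consumed and per
cmol supplied — the two coincide when uptake saturates its bound.
Reproductions of the published genome-scale comparison on the bundled core
model are qualitative (the ordering), since the exact biomass and TAG
equations of the genome-scale model are only available from its external
distribution.

# Sequence triage

## Alignment and identity

Pairwise global alignment uses Needleman–Wunsch with affine gaps (BLOSUM62,
gap open 11, extend 1; a gap of length $L$ costs $11 + L$), computed by
Biostrings. Identity is the fraction of matching columns among alignment
columns *excluding terminal gaps* (BLAST-like); a shorter-sequence
denominator is available as an option since clustering tools vary in this
convention.

## Clustering and neighbour joining

[`cluster_by_identity()`] reproduces the greedy, representative-based
scheme of BLASTclust-style redundancy removal: sequences are visited in
order of decreasing length (id as tiebreak) and join the first
representative they match at ≥ the threshold (default 0.90), so the result
is deterministic and independent of input order.

[`nj_tree()`] is an independent implementation of Saitou–Nei neighbour
joining (ape's implementation serves as a cross-check in the tests, never
as the computation): the Q-criterion selects each join, ties break on the
lexicographically first pair, and negative branch-length estimates are
clamped to zero with the deficit moved to the sibling edge, preserving the
path length between the joined leaves. On additive matrices the output
reproduces the input distances exactly (to 10^-9^). Distances default to
raw p-distances (1 − identity) without a multiple-hit correction — at the
divergences relevant for candidate triage the correction is small, and the
choice is explicit rather than buried in a tool default.

Newick output formats branch lengths with 10 significant digits by default
(6 is available via the `digits` argument but cannot guarantee round-trip
fidelity at the 10^-9^ level, so fidelity won over compactness).

# What the synthetic generators emulate — and what they do not

* `generate_thermo_records()` draws Gaussian estimates around a known
  value with stated per-record sigmas: the statistical structure of a
  literature compilation, without its systematic errors or correlated
  biases. Passing the recovery tests shows the estimator is correct, not
  that real literature data are this well behaved.
* `generate_protein_family()` evolves sequences along a known tree under a
  uniform 20-letter substitution model with per-site substitution
  probability per unit branch length — no rate heterogeneity across sites,
  no indels, no compositional bias. That is sufficient to exercise
  clustering and topology recovery; real protein families are harder, and
  recovery rates measured here do not transfer to them. With 8 taxa,
  200 residues and rate 0.05 the NJ stage recovers the generating topology
  in essentially all seeded replicates (the acceptance script recomputes
  the rate over 50 replicates).
* `generate_core_model()` stands in for a genome-scale model: it preserves
  the pathway-level economics (carbon routing, cofactor costs, P/O) but
  none of the gene-level detail, so absolute growth rates are not
  comparable to genome-scale predictions — only orderings and yield logic
  are.

# Numerical choices

* LP tolerances: feasibility 10^-9^ on bounds, 10^-6^ on the objective and
  steady state; the simplex uses a 10^-9^ pivot tolerance.
* `reconcile()` floors the Birge ratio at 1 (stated uncertainties are
  never deflated).
* Heat-capacity integrals are closed-form; no quadrature at run time.
* The mass-balance equilibrium root is bracketed in
  $(0, \min([\mathrm{MeOH}], [\mathrm{NAD}^+]))$ and solved by `uniroot`
  at 10^-15^ tolerance.
* Degenerate inputs fail early with named offenders: dangling metabolites,
  duplicated ids, inverted bounds, asymmetric distance matrices,
  unbalanced Newick parentheses (with a character position).

# Known limitations

* No gene–protein–reaction logic, thermodynamic-FBA coupling, or dynamic
  FBA; the stoichiometric comparison cannot see enzyme capacity or
  expression limits — precisely the factors the wet-lab side of this
  problem ran into.
* No group-contribution estimation or activity-coefficient models; the
  thermodynamic stage is only as good as its formation table.
* The SBML reader covers Level 3 core with fbc bounds; exotic dialects
  should be converted to the tabular format first.
* The simplex kernel is dense and pure R: adequate below ~100 reactions,
  not intended for genome-scale models.
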