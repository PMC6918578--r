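# methylopath

In silico evaluation of synthetic methanol and formaldehyde assimilation in
oleaginous yeast (*Yarrowia lipolytica*), for metabolic engineers deciding
whether — and through which pathway — a non-methylotrophic host could use
methanol as a carbon source.

The package covers the three desk-scale stages of that decision:

1. **Thermodynamics of methanol oxidation.** Aqueous formaldehyde is an
   equilibrium pool of free HCHO and methylene glycol CH₂(OH)₂; the pool's
   chemical potential is ΔfG_pool(T) = −RT·ln Σᵢ exp(−ΔfGᵢ/RT). Literature
   formation estimates are reconciled by inverse-variance weighting with
   Birge-ratio inflation, Gibbs energies are extrapolated over temperature
   with the Gibbs–Helmholtz relation (closed-form heat-capacity
   integrals), and the equilibrium formaldehyde concentration of the
   NAD-dependent alcohol-dehydrogenase reaction,
   [HCHO-pool] = K(T)·[MeOH]·[NAD⁺]/[NADH], is tabulated per temperature.
2. **Constraint-based pathway comparison.** Flux balance analysis
   (maximise c′v subject to S·v = 0, lb ≤ v ≤ ub) on a stoichiometric
   model extended with the RuMP pathway (HPS + PHI), the XuMP pathway
   (DHAS + DAK) or the alpha-proteobacterial serine cycle, under growth
   and triacylglycerol objectives, with flux variability analysis for
   alternate optima and carbon-yield/oxygen-demand accounting. A reduced
   yeast-like core model (~40 reactions, bundled) makes the comparison
   reproducible without downloads.
3. **HPS candidate triage.** Global pairwise alignment (Needleman–Wunsch,
   affine gaps, BLOSUM62), BLASTclust-style greedy clustering at 90%
   identity, and Saitou–Nei neighbour joining with Newick output.

## Worked example

```r
library(methylopath)

## 1. Equilibrium formaldehyde from 0.5 M methanol, NAD+/NADH = 1
thermo_report(temperatures_c = c(28, 30, 50))
#>   temperature_C delta_r_g_kJ_mol            K hcho_pool_uM
#> 1            28         24.02610 6.800000e-05     34.00000
#> 2            30         23.79263 7.947546e-05     39.73773
#> 3            50         21.45726 3.400000e-04    170.00000
```

Even at 50 °C the reaction stays strongly endergonic (ΔrG ≈ +21 kJ/mol):
an equilibrium of only ~170 µM formaldehyde from 0.5 M methanol, and ~34 µM
at growth temperature — which is why a strong downstream pull (an active
HPS) matters more than the dehydrogenase itself.

```r
## 2. Pathway comparison on the bundled core model, methanol uptake 6
cmp <- compare_pathways(generate_core_model(), uptake = 6)
cmp[, c("pathway", "objective", "objective_value", "carbon_yield", "oxygen_demand")]
#>        pathway objective objective_value carbon_yield oxygen_demand
#> 1         RuMP    growth      0.80862534    0.9433962     0.6064690
#> 2         RuMP       TAG      0.05607477    0.5140187     0.7429907
#> 3         XuMP    growth      0.70404172    0.8213820     0.7220339
#> 4         XuMP       TAG      0.05607477    0.5140187     0.7429907
#> 5 serine_cycle    growth      0.66138646    0.7716175     0.7691680
#> 6 serine_cycle       TAG      0.07527881    0.6900558     0.4837361
```

All three extensions let the model grow on methanol as sole carbon source
(without one, growth is exactly zero). Growth ranks RuMP > XuMP > serine
cycle: XuMP pays one ATP per formaldehyde at the dihydroxyacetone kinase,
the serine cycle two ATP and two NADH per acetyl unit. TAG carbon yields
for RuMP and XuMP coincide (their net carbon stoichiometries are
identical); objective values are `h⁻¹`-scale biomass flux and cmol/cmol
yields respectively.

```r
## 3. Cluster synthetic HPS candidates and build the NJ tree
fam <- generate_protein_family(family_params(n_taxa = 8, seed = 3))
cluster_by_identity(fam$sequences, threshold = 0.9)   # 6 clusters
tree <- nj_tree(identity_distances(fam$sequences))
write_newick(tree)
```

A command-line front end wrapping the same functions is installed at
`system.file("scripts", "methylopath", package = "methylopath")`, with
subcommands `thermo-report`, `compare`, `hps-cluster`, `synth` and `run`
(YAML config; exit codes 0 ok / 2 config error / 3 infeasible).

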