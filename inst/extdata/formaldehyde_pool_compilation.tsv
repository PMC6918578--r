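# Synthetic literature-style compilation of independent estimates of the
# formation Gibbs energy of the aqueous formaldehyde/methylene-glycol pool.
# Constructed so that inverse-variance reconciliation with Birge inflation
# reproduces the published consensus 130.54 +/- 3.3 kJ/mol.
species_id	property	value	uncertainty	T_ref	source
formaldehyde_pool	formation_gibbs	134.997602	5	298.15	calorimetric_A
formaldehyde_pool	formation_gibbs	124.121053	6	298.15	equilibrium_B
formaldehyde_pool	formation_gibbs	136.334883	8	298.15	spectroscopic_C
formaldehyde_pool	formation_gibbs	123.205851	9	298.15	equilibrium_D
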