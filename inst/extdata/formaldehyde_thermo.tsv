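# Reference formation data for the methanol / formaldehyde / NAD system.
# Transformed standard state (pH-dependent, water at unit activity); the
# NAD+ couple anchors the convention (NAD+ set to zero). Values encode the
# reconciled formation Gibbs energy of the aqueous formaldehyde /
# methylene-glycol pool (130.54 +/- 3.3 kJ/mol at 298.15 K, hydration
# constant ~2.3e3) and reaction enthalpies consistent with the observed
# temperature dependence of the alcohol-dehydrogenase equilibrium.
# Units: kJ/mol (value, uncertainty); T_ref in K.
species_id	property	value	uncertainty	T_ref	source
methanol	formation_gibbs	128.813716054	0.5	298.15	reconciled_reference
methanol	formation_enthalpy	-274.103529553	1.0	298.15	reconciled_reference
formaldehyde	formation_gibbs	149.728784279	5.0	298.15	reconciled_reference
formaldehyde	formation_enthalpy	-150.0	5.0	298.15	reconciled_reference
methylene_glycol	formation_gibbs	130.541077513	3.3	298.15	reconciled_reference
methylene_glycol	formation_enthalpy	-183.0	5.0	298.15	reconciled_reference
nad_ox	formation_gibbs	0.0	0	298.15	convention_anchor
nad_ox	formation_enthalpy	0.0	0	298.15	convention_anchor
nad_red	formation_gibbs	22.65	0.1	298.15	convention_anchor
nad_red	formation_enthalpy	-31.94	0.5	298.15	convention_anchor
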