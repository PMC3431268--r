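# Reference flux distributions for a fermenting S. cerevisiae strain with an
# engineered NADPH-dependent butanediol dehydrogenase, at four levels of
# imposed NADPH demand (0, 100, 200, 300 mM acetoin in the medium).
# Pathway fluxes are mol per 100 mol glucose consumed; glucose uptake is the
# specific rate in mmol/gDW/h. 'reaction' maps each row onto the packaged
# network ('tk_total' = summed flux of the two transketolase reactions;
# 'uptake_rate' is a scale annotation only). sd columns are the reported
# between-convergent-solution standard deviations.
name	reaction	a0	sd0	a100	sd100	a200	sd200	a300	sd300
glucose_uptake_mmol_gDW_h	uptake_rate	17.8	NA	19.5	NA	19.6	NA	25.7	NA
glycolysis	pgi	84.7	0.9	78.8	1.9	69.9	0.6	65.2	0.6
ppp	zwf	11.4	0.9	18	1.9	26	0.9	33.0	1.4
transketolase	tk_total	5.6	1.5	9.0	2.5	12.2	2.7	18.6	4.2
biomass_carbohydrates	carb_bm	3.3	0.1	3.4	0.1	2.5	0.1	2.1	0.1
pyruvate_decarboxylase	pdc	164.3	0.1	164.8	0.5	167.1	0.1	167.9	0.4
pyruvate_carboxylase	pyc	4.2	0.8	2.7	0.7	2.1	0.6	2.5	0.6
oaa_mito_import	oaa_tm	3.4	0.8	2	0.7	1.6	0.6	2	0.6
acetaldehyde_dehydrogenase	ald6	2.4	0.1	3.8	0.06	4.2	0.1	5.6	0.1
biomass_lipids	lip_bm	0.29	0.01	0.17	0.02	0.15	0.02	0.09	0.04
acetyl_coa_synthetase	acs	0.30	0.03	0.20	0.06	0.22	0.1	0.13	0.09
ethanol_production	etoh_out	161.9	0.1	161	0.5	162.9	0.5	162.3	0.5
glycerol_production	glyc_out	17.8	0.1	17.9	0.1	14.7	0.1	13.7	0.1
acetate_production	ace_out	2.1	0.1	3.6	0.1	4.0	0.1	5.5	0.1
succinate_production	succ_out	0.30	0.01	0.26	0.01	0.26	0.01	0.28	0.01
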