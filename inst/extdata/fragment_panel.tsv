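# emuflux default GC-MS fragment panel: 25 summed-fractional-labeling (SFL) targets.
# One glucose derivative (glucose pentaacetate) and two amino-acid derivative
# families (ECF = ethyl chloroformate, DMFDMA = dimethylformamide dimethyl
# acetal) of proteinogenic amino acids hydrolysed from biomass.
# The panel composition is a packaged, documented default reconstruction:
# the measured fragment list of the original study is not public.
# fragment: id; metabolite: model species carrying the carbon skeleton;
# positions: backbone carbons covered by the fragment (1 = carboxyl/aldehyde);
# moiety: elemental composition of all derivatization / non-backbone atoms
# contributing isotope mass (used for natural-abundance correction);
# family: derivative family tag.
fragment	metabolite	positions	moiety	family
glcpa_1_6	GLC.ext	1,2,3,4,5,6	C10H14O9	glcpa
glcpa_2_6	GLC.ext	2,3,4,5,6	C8H11O7	glcpa
ala_1_3	ALA	1,2,3	C5H12NO4	ecf
ala_2_3	ALA	2,3	C3H9NO2	ecf
val_1_5	VAL	1,2,3,4,5	C5H12NO4	ecf
val_2_5	VAL	2,3,4,5	C3H9NO2	ecf
leu_1_6	LEU	1,2,3,4,5,6	C5H12NO4	ecf
leu_2_6	LEU	2,3,4,5,6	C3H9NO2	ecf
ile_1_6	ILE	1,2,3,4,5,6	C5H12NO4	ecf
ile_2_6	ILE	2,3,4,5,6	C3H9NO2	ecf
gly_1_2	GLY	1,2	C5H12NO4	ecf
ser_1_3	SER	1,2,3	C5H12NO4	ecf
ser_2_3	SER	2,3	C3H9NO2	ecf
thr_1_4	THR	1,2,3,4	C4H12N2O2	dmfdma
thr_2_4	THR	2,3,4	C3H9N2	dmfdma
asp_1_4	ASP	1,2,3,4	C4H12N2O2	dmfdma
asp_2_4	ASP	2,3,4	C3H9N2	dmfdma
glu_1_5	GLU	1,2,3,4,5	C4H12N2O2	dmfdma
glu_2_5	GLU	2,3,4,5	C3H9N2	dmfdma
phe_1_9	PHE	1,2,3,4,5,6,7,8,9	C4H12N2O2	dmfdma
phe_2_9	PHE	2,3,4,5,6,7,8,9	C3H9N2	dmfdma
tyr_1_9	TYR	1,2,3,4,5,6,7,8,9	C4H12N2O2	dmfdma
tyr_2_9	TYR	2,3,4,5,6,7,8,9	C3H9N2	dmfdma
lys_1_6	LYS	1,2,3,4,5,6	C4H12N2O2	dmfdma
lys_2_6	LYS	2,3,4,5,6	C3H9N2	dmfdma
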