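# emuflux network definition: fermentative S. cerevisiae central carbon metabolism
# Sections start with '@'. Fields are TAB separated.
# @metabolites: name, carbons, role (substrate | balanced | external)
# @reactions:   id, equation ('-->'), atoms ('lhs : rhs', one lower-case letter
#               group per metabolite instance, '.' = unmapped external sink),
#               reversible (yes/no), compartment (c/m/e), cofactors
#               (comma-separated name=coefficient per unit net flux, '-' = none)
# Carbon atoms are numbered from the carbonyl/carboxyl end (glucose C1 = aldehyde).
@metabolites
GLC.ext	6	substrate
G6P	6	balanced
PG6	6	balanced
F6P	6	balanced
DHAP	3	balanced
GAP	3	balanced
PGA	3	balanced
PEP	3	balanced
PYR.c	3	balanced
Ru5P	5	balanced
X5P	5	balanced
R5P	5	balanced
S7P	7	balanced
E4P	4	balanced
GLYC	3	balanced
ACALD	2	balanced
ETOH	2	balanced
ACE	2	balanced
ACCOA.c	2	balanced
OAA.c	4	balanced
PYR.m	3	balanced
ACCOA.m	2	balanced
OAA.m	4	balanced
AKG	5	balanced
SUCC	4	balanced
CO2	1	balanced
MTHF	1	balanced
ALA	3	balanced
VAL	5	balanced
LEU	6	balanced
ILE	6	balanced
THR	4	balanced
ASP	4	balanced
GLU	5	balanced
SER	3	balanced
GLY	2	balanced
PHE	9	balanced
TYR	9	balanced
LYS	6	balanced
CO2.ext	1	external
ETOH.ext	2	external
GLYC.ext	3	external
AC.ext	2	external
SUCC.ext	4	external
ACALD.ext	2	external
ACT.ext	4	external
BTD.ext	4	external
BIOMASS	0	external
@reactions
glk	GLC.ext --> G6P	abcdef : abcdef	no	c	atp=-1
pgi	G6P --> F6P	abcdef : abcdef	yes	c	-
fba	F6P --> DHAP + GAP	abcdef : cba + def	no	c	atp=-1
tpi	DHAP --> GAP	abc : abc	yes	c	-
gapdh	GAP --> PGA	abc : abc	yes	c	nadh=1,atp=1
eno	PGA --> PEP	abc : abc	yes	c	-
pyk	PEP --> PYR.c	abc : abc	no	c	atp=1
zwf	G6P --> PG6	abcdef : abcdef	no	c	nadph=1
gnd	PG6 --> Ru5P + CO2	abcdef : bcdef + a	no	c	nadph=1
rpe	Ru5P --> X5P	abcde : abcde	yes	c	-
rpi	Ru5P --> R5P	abcde : abcde	yes	c	-
tkl1	X5P + R5P --> S7P + GAP	abcde + fghij : abfghij + cde	yes	c	-
tal	S7P + GAP --> E4P + F6P	abcdefg + hij : defg + abchij	yes	c	-
tkl2	X5P + E4P --> F6P + GAP	abcde + fghi : abfghi + cde	yes	c	-
gpd	DHAP --> GLYC	abc : abc	no	c	nadh=-1
glyc_out	GLYC --> GLYC.ext	abc : abc	no	e	-
pdc	PYR.c --> ACALD + CO2	abc : bc + a	no	c	-
adh	ACALD --> ETOH	ab : ab	no	c	nadh=-1
etoh_out	ETOH --> ETOH.ext	ab : ab	no	e	-
ald6	ACALD --> ACE	ab : ab	no	c	nadph=1
ace_out	ACE --> AC.ext	ab : ab	no	e	-
acs	ACE --> ACCOA.c	ab : ab	no	c	atp=-2
pyc	PYR.c + CO2 --> OAA.c	abc + d : abcd	no	c	atp=-1
oaa_tm	OAA.c --> OAA.m	abcd : abcd	no	m	-
pyr_tm	PYR.c --> PYR.m	abc : abc	no	m	-
pdh	PYR.m --> ACCOA.m + CO2	abc : bc + a	no	m	nadh=1
cs_idh	OAA.m + ACCOA.m --> AKG + CO2	abcd + ef : dcbfe + a	no	m	nadh=1
kgd	AKG --> SUCC + CO2	abcde : bcde + a	no	m	nadh=1,atp=1
succ_out	SUCC --> SUCC.ext	abcd : abcd	no	e	-
co2_out	CO2 --> CO2.ext	a : a	no	e	-
acald_out	ACALD --> ACALD.ext	ab : ab	no	e	-
bdh	ACT.ext --> BTD.ext	abcd : abcd	no	c	nadph=-1
ala_syn	PYR.c --> ALA	abc : abc	no	c	nadph=-1
val_syn	2 PYR.c --> VAL + CO2	abc + def : abefc + d	no	m	nadph=-2
leu_syn	2 PYR.c + ACCOA.m --> LEU + 2 CO2	abc + def + gh : ghbefc + a + d	no	m	nadph=-2
ile_syn	OAA.c + PYR.c --> ILE + CO2	abcd + efg : abfcdg + e	no	m	nadph=-3
thr_syn	OAA.c --> THR	abcd : abcd	no	c	nadph=-3
asp_syn	OAA.c --> ASP	abcd : abcd	no	c	nadph=-1
glu_syn	AKG --> GLU	abcde : abcde	no	m	nadph=-1
ser_syn	PGA --> SER	abc : abc	no	c	nadph=-1
gly_syn	SER --> GLY + MTHF	abc : ab + c	no	c	-
phe_syn	2 PEP + E4P --> PHE + CO2	abc + def + ghij : defbcghij + a	no	c	nadph=-1
tyr_syn	2 PEP + E4P --> TYR + CO2	abc + def + ghij : defbcghij + a	no	c	nadph=-1
lys_syn	AKG + ACCOA.m --> LYS + CO2	abcde + fg : edcbgf + a	no	m	nadph=-4
ala_bm	ALA --> BIOMASS	abc : .	no	e	-
val_bm	VAL --> BIOMASS	abcde : .	no	e	-
leu_bm	LEU --> BIOMASS	abcdef : .	no	e	-
ile_bm	ILE --> BIOMASS	abcdef : .	no	e	-
thr_bm	THR --> BIOMASS	abcd : .	no	e	-
asp_bm	ASP --> BIOMASS	abcd : .	no	e	-
glu_bm	GLU --> BIOMASS	abcde : .	no	e	-
ser_bm	SER --> BIOMASS	abc : .	no	e	-
gly_bm	GLY --> BIOMASS	ab : .	no	e	-
phe_bm	PHE --> BIOMASS	abcdefghi : .	no	e	-
tyr_bm	TYR --> BIOMASS	abcdefghi : .	no	e	-
lys_bm	LYS --> BIOMASS	abcdef : .	no	e	-
carb_bm	G6P --> BIOMASS	abcdef : .	no	e	-
lip_bm	ACCOA.c --> BIOMASS	ab : .	no	e	nadph=-2
nucl_bm	R5P --> BIOMASS	abcde : .	no	e	nadph=-1
c1_bm	MTHF --> BIOMASS	a : .	no	e	-
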