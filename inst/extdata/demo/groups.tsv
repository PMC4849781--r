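group	parameter	weight
glctr	glctr.Vmax	4e-11
gk	gka.Vmax	1.2e-12
gk	gkb.Vmax	1.2e-12
g6pase	g6pasea.Vmax	8e-13
g6pase	g6paseb.Vmax	8e-13
pfk	pfka.Vmax	1e-12
pfk	pfkb.Vmax	1e-12
fbase	fbasea.Vmax	4e-13
fbase	fbaseb.Vmax	4e-13
aldo	aldo1.Vmax	3e-12
aldo	aldo2.Vmax	6e-12
aldo	aldo3.Vmax	8e-13
fru_uptake	frutr.Vmax	2.5e-11
fru_uptake	fruhk.Vmax	8e-12
trik	trik.Vmax	2.5e-12
glycolysis_lower	gapdh.Vmax	4e-11
glycolysis_lower	pgk.Vmax	1.2e-11
pk	pk.Vmax	6e-12
lactate_out	ldh.Vmax	1e-11
lactate_out	lactr.Vmax	8e-12
gs	gs.Vmax	3e-12
gp	gp.Vmax	3e-13
atp_demand	atpase.Vmax	3e-12
oxphos	oxphos.Vmax	1.2e-11
oxphos	antr.Vmax	1.2e-11
oxphos	pitr.Vmax	4e-11
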