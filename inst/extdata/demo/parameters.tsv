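parameter	value
glctr.Vmax	4e-11
glctr.Ks.eGlc	17
glctr.Kp.Glc	17
glctr.Keq	1
gka.Vmax	1.2e-12
gka.Km	7.5
gka.KmATP	0.4
gka.Ki	0.03
gka.Kir	0.01
gkb.Vmax	1.2e-12
gkb.Km	7.5
gkb.KmATP	0.4
gkb.Ki	0.03
gkb.Kir	0.01
g6pasea.Vmax	8e-13
g6pasea.Km.G6Pa	2
g6paseb.Vmax	8e-13
g6paseb.Km.G6Pb	2
gpia.Vmax	1e-10
gpia.Ks.G6Pa	0.3
gpia.Kp.F6Pa	0.15
gpia.Keq	0.3
gpib.Vmax	1e-10
gpib.Ks.G6Pb	0.3
gpib.Kp.F6Pb	0.15
gpib.Keq	0.3
pfka.Vmax	1e-12
pfka.Km.F6Pa	0.1
pfka.Km.cATP	0.15
pfkb.Vmax	1e-12
pfkb.Km.F6Pb	0.1
pfkb.Km.cATP	0.15
fbasea.Vmax	4e-13
fbasea.Km.FBPa	0.01
fbaseb.Vmax	4e-13
fbaseb.Km.FBPb	0.01
aldo1.Vmax	3e-12
aldo1.Ks.FBPa	0.01
aldo1.Kp.DHAP	2
aldo1.Kp.GAP	1
aldo1.Keq	0.068
aldo1.Ki.F1P	2
aldo2.Vmax	6e-12
aldo2.Ks.F1P	1
aldo2.Kp.DHAP	2
aldo2.Kp.GA	1
aldo2.Keq	0.1
aldo2.Ki.FBPa	0.3
aldo3.Vmax	8e-13
aldo3.Ks.FBPa	0.01
aldo3.Ks.GA	1
aldo3.Kp.F1P	1
aldo3.Kp.GAP	1
aldo3.Keq	1
tim.Vmax	1e-10
tim.Ks.DHAP	0.6
tim.Kp.GAP	0.4
tim.Keq	0.045
frutr.Vmax	2.5e-11
frutr.Ks.eFru	67
frutr.Kp.Fru	67
frutr.Keq	1
fruhk.Vmax	8e-12
fruhk.Km.Fru	0.5
fruhk.Km.cATP	0.4
trik.Vmax	2.5e-12
trik.Km.GA	0.05
trik.Km.cATP	0.1
gapdh.Vmax	4e-11
gapdh.Ks.GAP	0.05
gapdh.Ks.cNAD	0.05
gapdh.Ks.cPi	1.5
gapdh.Kp.BPG	0.01
gapdh.Kp.cNADH	0.01
gapdh.Keq	0.01
pgk.Vmax	1.2e-11
pgk.Ks.BPG	0.005
pgk.Ks.cADP	0.05
pgk.Kp.PG3	0.5
pgk.Kp.cATP	0.3
pgk.Keq	1600
pgm.Vmax	2e-11
pgm.Ks.PG3	0.2
pgm.Kp.PG2	0.05
pgm.Keq	0.12
eno.Vmax	2e-11
eno.Ks.PG2	0.05
eno.Kp.PEP	0.15
eno.Keq	4.6
pk.Vmax	6e-12
pk.Km.PEP	0.8
pk.Km.cADP	0.05
ldh.Vmax	1e-11
ldh.Ks.Pyr	0.3
ldh.Ks.cNADH	0.002
ldh.Kp.Lac	10
ldh.Kp.cNAD	0.2
ldh.Keq	3600
lactr.Vmax	8e-12
lactr.Ks.Lac	3
lactr.Kp.eLac	3
lactr.Keq	1
pglm.Vmax	1e-11
pglm.Ks.G6Pb	0.1
pglm.Kp.G1P	0.05
pglm.Keq	0.06
gs.Vmax	3e-12
gs.Km.G1P	0.1
gs.Km.cATP	0.5
gp.Vmax	3e-13
gp.Km.Glyc	2
gp.Km.cPi	4
ppase.Vmax	2e-11
ppase.Km.cPPi	0.05
atpase.Vmax	3e-12
atpase.Km.cATP	1
adk.k	5e-11
adk.kr	5e-11
nadhox.Vmax	5e-13
nadhox.Km.cNADH	0.01
pitr.Vmax	4e-11
pitr.Ks.cPi	1
pitr.Kp.mPi	1
pitr.Keq	1
antr.Vmax	1.2e-11
antr.Ks.mATP	0.1
antr.Ks.cADP	0.25
antr.Kp.cATP	0.5
antr.Kp.mADP	0.5
antr.Keq	1
oxphos.Vmax	1.2e-11
oxphos.Km.mADP	0.3
oxphos.Km.mPi	1.5
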