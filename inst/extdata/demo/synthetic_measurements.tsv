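condition_id	observable_id	metabolite	fragment	isotopologue_index	time_min	value	sd
A1	eGlc.conc	eGlc		conc	120	18.0826040664489	0.181965973439354
A1	eLac.conc	eLac		conc	120	2.97316963622967	0.0296771961727092
A1	Glyc.conc	Glyc		conc	120	14.7445802766423	0.148688284615976
A1	eGlc.C1-C6.m0	eGlc	C1-C6	0	120	0.518621506919793	0.01
A1	eGlc.C1-C6.m1	eGlc	C1-C6	1	120	0.00329507771815361	0.01
A1	eGlc.C1-C6.m2	eGlc	C1-C6	2	120	0.489093270979376	0.01
A1	eGlc.C1-C6.m3	eGlc	C1-C6	3	120	0.00487429052428485	0.01
A1	eGlc.C1-C6.m4	eGlc	C1-C6	4	120	0.00741659333232074	0.01
A1	eGlc.C1-C6.m5	eGlc	C1-C6	5	120	0.00575781351653492	0.01
A1	eGlc.C1-C6.m6	eGlc	C1-C6	6	120	0	0.01
A1	Glyc.C1-C4.m0	Glyc	C1-C4	0	120	0.585189425371542	0.01
A1	Glyc.C1-C4.m1	Glyc	C1-C4	1	120	0.0043615974000121	0.01
A1	Glyc.C1-C4.m2	Glyc	C1-C4	2	120	0.423210678134545	0.01
A1	Glyc.C1-C4.m3	Glyc	C1-C4	3	120	0	0.01
A1	Glyc.C1-C4.m4	Glyc	C1-C4	4	120	0.0112493091814311	0.01
A1	Glyc.C3-C6.m0	Glyc	C3-C6	0	120	0.999045361536844	0.01
A1	Glyc.C3-C6.m1	Glyc	C3-C6	1	120	0	0.01
A1	Glyc.C3-C6.m2	Glyc	C3-C6	2	120	0.00994366447985647	0.01
A1	Glyc.C3-C6.m3	Glyc	C3-C6	3	120	0.00821221195098088	0.01
A1	Glyc.C3-C6.m4	Glyc	C3-C6	4	120	0.00593901321217509	0.01
A1	eLac.C1-C3.m0	eLac	C1-C3	0	120	0.941763448323331	0.01
A1	eLac.C1-C3.m1	eLac	C1-C3	1	120	0.00782136300731067	0.01
A1	eLac.C1-C3.m2	eLac	C1-C3	2	120	0.0681719752264034	0.01
A1	eLac.C1-C3.m3	eLac	C1-C3	3	120	0	0.01
A1	sorbitol.C1-C6.m0	sorbitol	C1-C6	0	120	0.55750356860763	0.01
A1	sorbitol.C1-C6.m1	sorbitol	C1-C6	1	120	0	0.01
A1	sorbitol.C1-C6.m2	sorbitol	C1-C6	2	120	0.447106648629336	0.01
A1	sorbitol.C1-C6.m3	sorbitol	C1-C6	3	120	0	0.01
A1	sorbitol.C1-C6.m4	sorbitol	C1-C6	4	120	0	0.01
A1	sorbitol.C1-C6.m5	sorbitol	C1-C6	5	120	0.00417941560199702	0.01
A1	sorbitol.C1-C6.m6	sorbitol	C1-C6	6	120	0.0135867955152904	0.01
A2	eGlc.conc	eGlc		conc	120	18.1778929354971	0.181965968038055
A2	eLac.conc	eLac		conc	120	2.97922709361345	0.0296772207760859
A2	Glyc.conc	Glyc		conc	120	14.8608287224152	0.1486882890184
A2	eGlc.C1-C6.m0	eGlc	C1-C6	0	120	0.983660389361226	0.01
A2	eGlc.C1-C6.m1	eGlc	C1-C6	1	120	0	0.01
A2	eGlc.C1-C6.m2	eGlc	C1-C6	2	120	0	0.01
A2	eGlc.C1-C6.m3	eGlc	C1-C6	3	120	0.00146852034817053	0.01
A2	eGlc.C1-C6.m4	eGlc	C1-C6	4	120	0.0110002537198388	0.01
A2	eGlc.C1-C6.m5	eGlc	C1-C6	5	120	0.00763175748457544	0.01
A2	eGlc.C1-C6.m6	eGlc	C1-C6	6	120	0	0.01
A2	Glyc.C1-C4.m0	Glyc	C1-C4	0	120	0.993957571722754	0.01
A2	Glyc.C1-C4.m1	Glyc	C1-C4	1	120	0.00836672719130322	0.01
A2	Glyc.C1-C4.m2	Glyc	C1-C4	2	120	0.00556663198673657	0.01
A2	Glyc.C1-C4.m3	Glyc	C1-C4	3	120	0	0.01
A2	Glyc.C1-C4.m4	Glyc	C1-C4	4	120	0	0.01
A2	Glyc.C3-C6.m0	Glyc	C3-C6	0	120	1	0.01
A2	Glyc.C3-C6.m1	Glyc	C3-C6	1	120	0.00909524615564773	0.01
A2	Glyc.C3-C6.m2	Glyc	C3-C6	2	120	0	0.01
A2	Glyc.C3-C6.m3	Glyc	C3-C6	3	120	0.010208170701798	0.01
A2	Glyc.C3-C6.m4	Glyc	C3-C6	4	120	0.00468285993180192	0.01
A2	eLac.C1-C3.m0	eLac	C1-C3	0	120	0.725996630087136	0.01
A2	eLac.C1-C3.m1	eLac	C1-C3	1	120	0.00341119691424425	0.01
A2	eLac.C1-C3.m2	eLac	C1-C3	2	120	0	0.01
A2	eLac.C1-C3.m3	eLac	C1-C3	3	120	0.282213342997366	0.01
A2	sorbitol.C1-C6.m0	sorbitol	C1-C6	0	120	0.968590531277454	0.01
A2	sorbitol.C1-C6.m1	sorbitol	C1-C6	1	120	0	0.01
A2	sorbitol.C1-C6.m2	sorbitol	C1-C6	2	120	0	0.01
A2	sorbitol.C1-C6.m3	sorbitol	C1-C6	3	120	0.00755723068653061	0.01
A2	sorbitol.C1-C6.m4	sorbitol	C1-C6	4	120	0	0.01
A2	sorbitol.C1-C6.m5	sorbitol	C1-C6	5	120	0.0240161776050478	0.01
A2	sorbitol.C1-C6.m6	sorbitol	C1-C6	6	120	0.0489610332681669	0.01
B	eGlc.conc	eGlc		conc	120	19.4977434435833	0.193641810645647
B	eLac.conc	eLac		conc	120	1.4621337651861	0.0146172445078446
B	Glyc.conc	Glyc		conc	120	3.48829397701091	0.035144156872631
B	eGlc.C1-C6.m0	eGlc	C1-C6	0	120	0.508477733862093	0.01
B	eGlc.C1-C6.m1	eGlc	C1-C6	1	120	0	0.01
B	eGlc.C1-C6.m2	eGlc	C1-C6	2	120	0.508062451885248	0.01
B	eGlc.C1-C6.m3	eGlc	C1-C6	3	120	0.00153253338211898	0.01
B	eGlc.C1-C6.m4	eGlc	C1-C6	4	120	0.0217294025670524	0.01
B	eGlc.C1-C6.m5	eGlc	C1-C6	5	120	0.00475509528899663	0.01
B	eGlc.C1-C6.m6	eGlc	C1-C6	6	120	0	0.01
B	Glyc.C1-C4.m0	Glyc	C1-C4	0	120	0.800738460967662	0.01
B	Glyc.C1-C4.m1	Glyc	C1-C4	1	120	0	0.01
B	Glyc.C1-C4.m2	Glyc	C1-C4	2	120	0.192785236283013	0.01
B	Glyc.C1-C4.m3	Glyc	C1-C4	3	120	0.00291531557432158	0.01
B	Glyc.C1-C4.m4	Glyc	C1-C4	4	120	0	0.01
B	Glyc.C3-C6.m0	Glyc	C3-C6	0	120	0.999963821234492	0.01
B	Glyc.C3-C6.m1	Glyc	C3-C6	1	120	0.000743413241516641	0.01
B	Glyc.C3-C6.m2	Glyc	C3-C6	2	120	0	0.01
B	Glyc.C3-C6.m3	Glyc	C3-C6	3	120	0	0.01
B	Glyc.C3-C6.m4	Glyc	C3-C6	4	120	0	0.01
B	eLac.C1-C3.m0	eLac	C1-C3	0	120	1	0.01
B	eLac.C1-C3.m1	eLac	C1-C3	1	120	0	0.01
B	eLac.C1-C3.m2	eLac	C1-C3	2	120	0.0167853204091651	0.01
B	eLac.C1-C3.m3	eLac	C1-C3	3	120	0.00332950371213518	0.01
B	sorbitol.C1-C6.m0	sorbitol	C1-C6	0	120	0.755198883328818	0.01
B	sorbitol.C1-C6.m1	sorbitol	C1-C6	1	120	0	0.01
B	sorbitol.C1-C6.m2	sorbitol	C1-C6	2	120	0.259130602093831	0.01
B	sorbitol.C1-C6.m3	sorbitol	C1-C6	3	120	0.00267098790772231	0.01
B	sorbitol.C1-C6.m4	sorbitol	C1-C6	4	120	0	0.01
B	sorbitol.C1-C6.m5	sorbitol	C1-C6	5	120	0.0120786780598317	0.01
B	sorbitol.C1-C6.m6	sorbitol	C1-C6	6	120	0.0116040261569495	0.01
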