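Gene ID	EC#	HMMER	dbCAN_sub	DIAMOND	#ofTools
g0001	3.2.1.4	GH5(35-340)	GH5_2(35-340)	GH5	3
g0002	3.2.1.8	GH10(12-310)	GH10_e12(12-310)	GH10	3
g0003	-	GH13(5-400)	GH13_8(5-400)	-	2
g0004	-	-	CE1_e4(10-220)	CE1	2
g0005	-	AA2(20-300)	-	-	1
g0006	-	GH5(1-250)+CBM2(260-340)	GH5_4(1-250)+CBM2_e1(260-340)	GH5	3
g0007	-	-	-	GH43	1
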