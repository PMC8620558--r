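toyM	0	68	tRNA-Phe	0	+	tRNA
toyM	70	1025	rRNA-12S	0	+	rRNA
toyM	1027	1096	tRNA-Val	0	+	tRNA
toyM	1098	2678	rRNA-16S	0	+	rRNA
toyM	2680	2755	tRNA-Leu1	0	+	tRNA
toyM	2757	3714	ND1	0	+	CDS
toyM	3716	3785	tRNA-Ile	0	+	tRNA
toyM	3787	3858	tRNA-Gln	0	-	tRNA
toyM	3860	3929	tRNA-Met	0	+	tRNA
toyM	3931	4969	ND2	0	+	CDS
toyM	4971	5038	tRNA-Trp	0	+	tRNA
toyM	5040	5109	tRNA-Ala	0	-	tRNA
toyM	5111	5182	tRNA-Asn	0	-	tRNA
toyM	5184	5251	tRNA-Cys	0	-	tRNA
toyM	5253	5321	tRNA-Tyr	0	-	tRNA
toyM	5323	6868	COX1	0	+	CDS
toyM	6870	6939	tRNA-Ser1	0	-	tRNA
toyM	6941	7011	tRNA-Asp	0	+	tRNA
toyM	7013	7697	COX2	0	+	CDS
toyM	7699	7764	tRNA-Lys	0	+	tRNA
toyM	7766	7970	ATP8	0	+	CDS
toyM	7972	8653	ATP6	0	+	CDS
toyM	8655	9438	COX3	0	+	CDS
toyM	9440	9508	tRNA-Gly	0	+	tRNA
toyM	9510	9858	ND3	0	+	CDS
toyM	9860	9928	tRNA-Arg	0	+	tRNA
toyM	9930	10227	ND4L	0	+	CDS
toyM	10229	11606	ND4	0	+	CDS
toyM	11608	11676	tRNA-His	0	+	tRNA
toyM	11678	11737	tRNA-Ser2	0	+	tRNA
toyM	11739	11810	tRNA-Leu2	0	+	tRNA
toyM	11812	13636	ND5	0	+	CDS
toyM	13638	14157	ND6	0	-	CDS
toyM	14159	14228	tRNA-Glu	0	-	tRNA
toyM	14230	15373	CYTB	0	+	CDS
toyM	15375	15442	tRNA-Thr	0	+	tRNA
toyM	15444	15511	tRNA-Pro	0	-	tRNA
toyM	15513	16390	D-loop	0	+	D-loop
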