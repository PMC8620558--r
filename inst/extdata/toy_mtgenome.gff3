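##gff-version 3
toyM	mitospectr	tRNA	1	68	.	+	.	ID=tRNA-Phe;Name=tRNA-Phe
toyM	mitospectr	rRNA	71	1025	.	+	.	ID=rRNA-12S;Name=rRNA-12S
toyM	mitospectr	tRNA	1028	1096	.	+	.	ID=tRNA-Val;Name=tRNA-Val
toyM	mitospectr	rRNA	1099	2678	.	+	.	ID=rRNA-16S;Name=rRNA-16S
toyM	mitospectr	tRNA	2681	2755	.	+	.	ID=tRNA-Leu1;Name=tRNA-Leu1
toyM	mitospectr	CDS	2758	3714	.	+	.	ID=ND1;Name=ND1
toyM	mitospectr	tRNA	3717	3785	.	+	.	ID=tRNA-Ile;Name=tRNA-Ile
toyM	mitospectr	tRNA	3788	3858	.	-	.	ID=tRNA-Gln;Name=tRNA-Gln
toyM	mitospectr	tRNA	3861	3929	.	+	.	ID=tRNA-Met;Name=tRNA-Met
toyM	mitospectr	CDS	3932	4969	.	+	.	ID=ND2;Name=ND2
toyM	mitospectr	tRNA	4972	5038	.	+	.	ID=tRNA-Trp;Name=tRNA-Trp
toyM	mitospectr	tRNA	5041	5109	.	-	.	ID=tRNA-Ala;Name=tRNA-Ala
toyM	mitospectr	tRNA	5112	5182	.	-	.	ID=tRNA-Asn;Name=tRNA-Asn
toyM	mitospectr	tRNA	5185	5251	.	-	.	ID=tRNA-Cys;Name=tRNA-Cys
toyM	mitospectr	tRNA	5254	5321	.	-	.	ID=tRNA-Tyr;Name=tRNA-Tyr
toyM	mitospectr	CDS	5324	6868	.	+	.	ID=COX1;Name=COX1
toyM	mitospectr	tRNA	6871	6939	.	-	.	ID=tRNA-Ser1;Name=tRNA-Ser1
toyM	mitospectr	tRNA	6942	7011	.	+	.	ID=tRNA-Asp;Name=tRNA-Asp
toyM	mitospectr	CDS	7014	7697	.	+	.	ID=COX2;Name=COX2
toyM	mitospectr	tRNA	7700	7764	.	+	.	ID=tRNA-Lys;Name=tRNA-Lys
toyM	mitospectr	CDS	7767	7970	.	+	.	ID=ATP8;Name=ATP8
toyM	mitospectr	CDS	7973	8653	.	+	.	ID=ATP6;Name=ATP6
toyM	mitospectr	CDS	8656	9438	.	+	.	ID=COX3;Name=COX3
toyM	mitospectr	tRNA	9441	9508	.	+	.	ID=tRNA-Gly;Name=tRNA-Gly
toyM	mitospectr	CDS	9511	9858	.	+	.	ID=ND3;Name=ND3
toyM	mitospectr	tRNA	9861	9928	.	+	.	ID=tRNA-Arg;Name=tRNA-Arg
toyM	mitospectr	CDS	9931	10227	.	+	.	ID=ND4L;Name=ND4L
toyM	mitospectr	CDS	10230	11606	.	+	.	ID=ND4;Name=ND4
toyM	mitospectr	tRNA	11609	11676	.	+	.	ID=tRNA-His;Name=tRNA-His
toyM	mitospectr	tRNA	11679	11737	.	+	.	ID=tRNA-Ser2;Name=tRNA-Ser2
toyM	mitospectr	tRNA	11740	11810	.	+	.	ID=tRNA-Leu2;Name=tRNA-Leu2
toyM	mitospectr	CDS	11813	13636	.	+	.	ID=ND5;Name=ND5
toyM	mitospectr	CDS	13639	14157	.	-	.	ID=ND6;Name=ND6
toyM	mitospectr	tRNA	14160	14228	.	-	.	ID=tRNA-Glu;Name=tRNA-Glu
toyM	mitospectr	CDS	14231	15373	.	+	.	ID=CYTB;Name=CYTB
toyM	mitospectr	tRNA	15376	15442	.	+	.	ID=tRNA-Thr;Name=tRNA-Thr
toyM	mitospectr	tRNA	15445	15511	.	-	.	ID=tRNA-Pro;Name=tRNA-Pro
toyM	mitospectr	D-loop	15514	16390	.	+	.	ID=D-loop;Name=D-loop
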