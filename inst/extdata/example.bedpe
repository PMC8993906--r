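chr1	149999	150000	chr1	154999	155000	sv1	.	+	-	P1	DEL
chr1	1199999	1200000	chr1	1214999	1215000	sv2	.	-	+	P1	DUP
chr1	1205999	1206000	chr1	1259999	1260000	sv3	.	+	+	P1	INV
chr1	2499999	2500000	chr2	899999	900000	sv4	.	+	-	P1	BND
chr1	152499	152500	chr1	171999	172000	sv5	.	+	-	P2	DEL
chr2	349999	350000	chr2	2349999	2350000	sv6	.	+	-	P2	DEL
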