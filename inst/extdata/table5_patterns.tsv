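amplicon	age	D	P	VC	E
NFM	P0	+	+	+	-
NFL	P0	+	+	+	±
MBP	P0	+	+	+	+
GFAP	P0	+	±	-	-
MPZ5p	P0	+	+	+	+
MPZ3p	P0	+	±	-	-
ACT	P0	+	+	+	±
ALB	P0	+	+	+	±
AFP	P0	+	+	+	±
NFM	P7	+	+	±	-
NFL	P7	+	+	±	-
MBP	P7	+	+	+	+
GFAP	P7	+	-	-	-
MPZ5p	P7	+	+	+	+
MPZ3p	P7	+	-	-	-
ACT	P7	+	+	+	-
ALB	P7	+	+	+	-
AFP	P7	+	+	+	-
NFM	P80	+	+	±	-
NFL	P80	+	+	+	±
MBP	P80	+	+	+	±
GFAP	P80	+	+	±	-
MPZ5p	P80	+	+	+	+
MPZ3p	P80	+	+	±	-
ACT	P80	+	+	+	-
ALB	P80	+	+	+	-
AFP	P80	+	+	+	-
NFM	P540	+	±	-	-
NFL	P540	+	±	-	-
MBP	P540	+	+	±	-
GFAP	P540	+	-	-	-
MPZ5p	P540	+	±	-	-
MPZ3p	P540	+	-	-	-
ACT	P540	+	±	-	-
ALB	P540	+	±	-	-
AFP	P540	+	±	-	-
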