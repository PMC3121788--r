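amplicon	length_bp	chromosome_label	accession	expressed
NFM	254	15p12	NM_017029	TRUE
NFL	249	14	X53981	TRUE
MBP	158	18q11-q13	K00512	NA
GFAP	418	10q32.1	Z48978	NA
MPZ5p	184	13q24-q25	NM_017027	NA
MPZ3p	291	13q24-q25	NM_017027	NA
ACT	254	12q11	M10277	TRUE
ALB	206	14p22	M16825	NA
AFP	252	14p21	J02816	FALSE
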