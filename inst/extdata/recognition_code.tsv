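# Default C2H2 recognition-code table: canonical residue -> preferred-base
# calls at the key helix positions, assembled from the classical
# Zif268-type code (Arg/Lys -> G via bidentate guanine contacts, Asn -> A,
# His -> G, Glu/Asp -> C, small/beta-branched residues -> T, Gln -> A).
# Position +2 rows give the base contacted on the COMPLEMENTARY strand;
# +10 rows apply to the extended contact of bulged-out helices.
# Replace or extend freely: the file, not the code, defines the mapping.
position	amino_acid	bases
-1	R	G
-1	K	GT
-1	Q	A
-1	N	A
-1	E	C
-1	D	C
-1	T	T
-1	S	T
-1	V	T
-1	A	T
+2	D	AC
+2	E	A
+2	S	T
+3	H	G
+3	N	A
+3	Q	A
+3	D	C
+3	E	C
+3	T	T
+3	S	T
+3	V	T
+3	A	T
+3	L	T
+6	R	G
+6	K	G
+6	Q	A
+6	N	A
+6	E	C
+6	D	C
+6	T	T
+6	S	T
+6	V	T
+10	R	G
+10	K	GT
+10	Q	A
+10	N	A
+10	E	C
+10	D	C
+10	T	T
+10	S	T
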