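# Y haplogroup tree covering the 12 major clades resolvable on the array's
# SNP panel plus their internal nodes.  One row per (node, defining SNP);
# nodes without defining SNPs (the root) carry NA in the SNP columns.
# Columns: node, parent (NA = root), snp_id, ancestral, derived.
node	parent	snp_id	ancestral	derived
ROOT	NA	NA	NA	NA
C-M130	ROOT	M130	C	T
DE-M145	ROOT	M145	A	G
D-M174	DE-M145	M174	T	C
E-M96	DE-M145	M96	G	C
F-M89	ROOT	M89	C	T
F-M89	ROOT	M213	T	C
GHIJKLT-F1329	F-M89	F1329	G	A
G-M201	GHIJKLT-F1329	M201	G	T
IJ-M429	GHIJKLT-F1329	M429	T	A
I-M170	IJ-M429	M170	A	C
J-M304	IJ-M429	M304	A	C
KLT-M9	GHIJKLT-F1329	M9	C	G
K-M526	KLT-M9	M526	T	G
NO-M214	K-M526	M214	A	C
O-M175	NO-M214	M175	T	C
P-P295	K-M526	P295	C	G
Q-M242	P-P295	M242	C	T
R-M207	P-P295	M207	A	G
R-M207	P-P295	M306	C	A
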