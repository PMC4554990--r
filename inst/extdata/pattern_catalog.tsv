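# Named MSY CNV pattern catalog (Repping-style nomenclature).
# One line per pattern: pattern<TAB>signature, where a signature is a
# "+"-separated list of region:state requirements with state in
# {del, dup, any}.  Regions not listed must be copy-normal for a match.
# The catalog is data, not code: edit or replace it to redefine patterns.
pattern	signature
gr/gr del (c8)	gr1:del+gr2:del
gr/gr dupl (c9)	gr1:dup+gr2:dup
b2/b3 del (c35)	U3:del+gr1:del
b1/b3 del (c3)	U3:del+gr1:del+b3:del
b2/b4 dupl (c21)	gr1:dup+b3:dup+Y1:dup+g2:dup+r3:dup+r4:dup+Y2:dup+b4:dup+gr2:dup
b2/b4 del + dupl (c9)	U3:del+gr1:del+b3:dup+Y1:dup+g2:dup+r3:dup+r4:dup+Y2:dup+b4:dup+gr2:dup
blue-grey dupl (c449)	U3:del+gr1:dup+gr2:dup
blue-grey like dupl	U3:del+gr1:dup+Y1:del+g2:del+r3:dup+r4:dup+Y2:del+gr2:dup
gr/gr dupl + distal dupl	gr1:dup+gr2:dup+distal:dup
distal gr dupl	gr2:dup
Y1/Y2 dupl	Y1:dup+Y2:dup
IR2 dupl	IR2:dup
IR2 del	IR2:del
P3 dupl	P3:dup+U1:dup
P3 del	P3:del+U1:del
P4 dupl	P4:dup
P5 dupl	P5:dup
P6 dupl	P6:dup
prior P5 post P4 dupl	preP5:dup+postP4:dup
q-arm dupl + U3 del	qprox:dup+U3:del
q-arm del	qprox:del
q-arm del + U3 del	qprox:del+U3:del
p-arm dupl (AMELY)	pAMELY:dup
p-arm dupl (PCDH11Y)	pPCDH:dup
p-arm dupl (TBL1Y)	pTBL1Y:dup
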