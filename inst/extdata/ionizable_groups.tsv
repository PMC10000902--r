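group	polarity	pka
nterm	basic	7.50
cterm	acidic	3.55
D	acidic	4.05
E	acidic	4.45
C	acidic	9.00
Y	acidic	10.00
H	basic	5.98
K	basic	10.00
R	basic	12.00
phospho1	acidic	1.20
phospho2	acidic	6.50
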