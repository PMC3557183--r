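# Raw (hydrogen-containing) ICRU-style elemental mass percentages for the two
# bundled reference tissues. Renormalising C/N/O over C+N+O yields the
# hydrogen-omitted compositions used for comparison with fitted count-rate
# fractions (hydrogen produces no positron emitter under (g,n) activation).
tissue	element	mass_percent
adipose_adult2	H	11.4
adipose_adult2	C	59.8
adipose_adult2	N	0.7
adipose_adult2	O	27.8
adipose_adult2	Na	0.1
adipose_adult2	S	0.1
adipose_adult2	Cl	0.1
urinary_bladder_filled	H	10.8
urinary_bladder_filled	C	3.5
urinary_bladder_filled	N	1.5
urinary_bladder_filled	O	83.0
urinary_bladder_filled	Na	0.3
urinary_bladder_filled	P	0.1
urinary_bladder_filled	S	0.1
urinary_bladder_filled	Cl	0.5
urinary_bladder_filled	K	0.2
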