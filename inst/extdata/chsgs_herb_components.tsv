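code	herb	n_components	n_active
CH	Bupleurum scorzonerifolium Willd.	354	79
CP	Citrus reticulata Blanco	74	14
CX	Ligusticum striatum DC.	193	35
XF	Cyperus rotundus L.	104	29
ZQ	Citrus x aurantium L.	17	6
SY	Paeonia lactiflora Pall.	166	45
GC	Glycyrrhiza uralensis Fisch. ex DC.	283	82
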