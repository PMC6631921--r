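# Published predictor scores for 16 rare/novel SERPINA1 missense SNVs
# (SVM pathogenicity probability, FoldX ddG in kcal/mol, PolyPhen-2 score).
# Variant strings as printed, mature numbering unless scheme says precursor.
variant	scheme	svm	foldx_ddg	polyphen2
P289S	mature	0.8282	3.49	1.000
I50N	mature	0.8153	2.69	1.000
D341V	mature	0.8651	0.99	0.998
M221T	mature	0.8186	2.93	0.997
V210E	mature	0.7162	1.37	0.818
P28L	mature	0.8205	1.17	0.648
P369H	mature	0.8784	3.36	1.000
A142D	mature	0.7958	1.03	0.992
M385 T	mature	0.8722	3.34	0.134
V333 M	mature	0.7237	-0.25	0.990
I9N	precursor	0.3387	N/A	0.517
Q40R	mature	0.6589	-0.35	0.018
K174E	mature	0.5053	0.21	0.030
H262Y	mature	0.6708	-0.68	0.040
E204K	mature	0.1021	-0.70	0.000
A325P	mature	0.0878	0.72	0.000
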