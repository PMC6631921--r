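# Published SERPINA1 benchmarking score table: 17 ClinVar pathogenic,
# 5 ClinVar benign and 35 primate-derived neutral variants with SVM
# probability, FoldX ddG (kcal/mol) and PolyPhen-2 score. Identity is the
# percent sequence identity of the source homolog (highest listed where a
# variant was found in several species); label is the benchmark truth.
variant	set	label	species	identity	svm	foldx_ddg	polyphen2
P369L	pathogenic_clinvar	pathogenic	Homo sapiens	100	0.8496	1.510	1.0000
P369S	pathogenic_clinvar	pathogenic	Homo sapiens	100	0.8353	4.410	1.0000
P369T	pathogenic_clinvar	pathogenic	Homo sapiens	100	0.8599	2.810	1.0000
M358R	pathogenic_clinvar	pathogenic	Homo sapiens	100	0.7853	0.431	0.0190
E342K	pathogenic_clinvar	pathogenic	Homo sapiens	100	0.8413	2.090	1.0000
E264V	pathogenic_clinvar	pathogenic	Homo sapiens	100	0.8619	1.660	1.0000
D256V	pathogenic_clinvar	pathogenic	Homo sapiens	100	0.8708	1.950	0.9850
G225R	pathogenic_clinvar	pathogenic	Homo sapiens	100	0.8975	5.160	0.9820
R223C	pathogenic_clinvar	pathogenic	Homo sapiens	100	0.8954	-0.350	0.9950
I92N	pathogenic_clinvar	pathogenic	Homo sapiens	100	0.8215	3.600	1.0000
G67E	pathogenic_clinvar	pathogenic	Homo sapiens	100	0.8680	26.290	1.0000
S53F	pathogenic_clinvar	pathogenic	Homo sapiens	100	0.8687	19.860	1.0000
L41P	pathogenic_clinvar	pathogenic	Homo sapiens	100	0.7585	3.240	0.6010
R39C	pathogenic_clinvar	pathogenic	Homo sapiens	100	0.8672	2.110	1.0000
A336T	pathogenic_clinvar	pathogenic	Homo sapiens	100	0.8479	3.450	1.0000
G115S	pathogenic_clinvar	pathogenic	Homo sapiens	100	0.7826	1.610	0.9990
F52S	pathogenic_clinvar	pathogenic	Homo sapiens	100	0.7900	6.020	1.0000
E376D	benign_clinvar	benign	Homo sapiens	N/A	0.2991	1.850	0
E363K	benign_clinvar	benign	Homo sapiens	N/A	0.4172	-0.900	0.11
A284S	benign_clinvar	benign	Homo sapiens	N/A	0.3445	-0.240	0.139
V213A	benign_clinvar	benign	Homo sapiens	N/A	0.1161	-0.100	0
R101H	benign_clinvar	benign	Homo sapiens	N/A	0.0576	-0.533	0
P21Q	primate	benign	Hylobates sp. ECACC	95	0.363	0.72	0.014
F23L	primate	benign	Papio anubis	92	0.3762	0.38	0
T27A	primate	benign	Gorilla gorilla	98	0.4118	1.34	0
N29K	primate	benign	Hylobates sp. ECACC	95	0.4365	-0.63	0.178
N29S	primate	benign	Papio anubis	92	0.0839	0.13	0
T48S	primate	benign	Hylobates sp. ECACC	95	0.4991	0.51	0
I50V	primate	benign	Gorilla gorilla	98	0.6687	0.96	0.767
D74S	primate	benign	Chlorocebus sabaeus	92	0.0588	0.38	0
N81H	primate	benign	Pongo abelii	96	0.462	0.27	0.007
I92V	primate	benign	Pongo abelii; Hylobates sp. ECACC	96	0.7931	1.06	0.006
Q105K	primate	benign	Papio anubis	92	0.2178	-0.5	0.001
N116S	primate	benign	Gorilla gorilla	98	0.751	1.9	0.311
K136N	primate	benign	Papio anubis	92	0.4292	0.07	0
E141D	primate	benign	Pongo abelii	96	0.4052	0.77	0.002
G148E	primate	benign	Chlorocebus sabaeus	92	0.219	-0.46	0
D159N	primate	benign	Papio anubis	92	0.165	-1.21	0
Q212E	primate	benign	Pongo abelii	96	0.2568	0.35	0
V213A	primate	benign	Hylobates sp. ECACC	95	0.1161	-0.1	0
Q230Y	primate	benign	Papio anubis	92	0.0803	0.49	0
Q230H	primate	benign	Hylobates sp. ECACC	95	0.0545	0.41	0
K233E	primate	benign	Papio anubis	92	0.0787	0.58	0
D270E	primate	benign	Hylobates sp. ECACC	95	0.2543	-0.03	0
I271V	primate	benign	Gorilla gorilla	98	0.1015	0.52	0
D280N	primate	benign	Pongo abelii	96	0.1407	0.82	0
S285N	primate	benign	Chlorocebus sabaeus	92	0.0554	-1.6	0
S292A	primate	benign	Chlorocebus sabaeus	92	0.3206	-0.14	0.003
S301R	primate	benign	Pongo abelii	96	0.1328	-0.54	0.011
S301T	primate	benign	Hylobates sp. ECACC	95	0.0724	0	0
S313G	primate	benign	Hylobates sp. ECACC	95	0.606	0.63	0.05
E324D	primate	benign	Chlorocebus sabaeus	92	0.0978	0.62	0
A332V	primate	benign	Homo sapiens	99	0.1255	1.88	0.99
I360V	primate	benign	Gorilla gorilla	98	0.1547	0.73	0
L383H	primate	benign	Hylobates sp. ECACC	95	0.8834	3.08	1
M385I	primate	benign	Papio anubis	92	0.7686	3.15	0.001
M385V	primate	benign	Pan troglodytes; Pongo abelii	99	0.7566	2.44	0.001
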