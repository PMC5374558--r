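host_genus	myoviruses	podoviruses	siphoviruses	other	entropy_reported
Bacillus	21	8	27	3	1.656
Escherichia	49	30	43	51	1.972
Lactococcus	0	25	30	0	0.472
Mycobacterium	10	0	206	2	0.384
Pseudomonas	38	29	21	8	1.829
Salmonella	10	19	21	4	1.789
Staphylococcus	19	4	35	5	1.535
Synechococcus	28	6	5	8	1.603
Vibrio	20	21	6	21	1.875
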