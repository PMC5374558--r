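host_genus	k4	k6	k8
Bacillus	0.342	0.558	1.146
Escherichia	0.372	0.706	1.416
Lactococcus	0.194	0.417	1.020
Mycobacterium	0.292	0.513	1.044
Pseudomonas	0.379	0.633	1.241
Salmonella	0.324	0.568	1.249
Staphylococcus	0.266	0.455	0.984
Synechococcus	0.335	0.516	0.986
Vibrio	0.371	0.658	1.360
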