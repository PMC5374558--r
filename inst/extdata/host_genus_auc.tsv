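host_genus	k4	k6	k8
Bacillus	0.856	0.863	0.823
Escherichia	0.878	0.858	0.807
Lactococcus	0.972	1.000	0.988
Mycobacterium	0.987	0.985	0.984
Pseudomonas	0.978	0.981	0.967
Salmonella	0.889	0.896	0.891
Staphylococcus	0.993	0.987	0.983
Synechococcus	0.965	0.978	0.955
Vibrio	0.936	0.940	0.892
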