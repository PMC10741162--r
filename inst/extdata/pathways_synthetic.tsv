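pathway_id	name	node_a	node_b
P_ARG_BIO	Arginine biosynthesis (synthetic toy topology)	C00064	C00025
P_ARG_BIO	Arginine biosynthesis (synthetic toy topology)	C00025	C00077
P_ARG_BIO	Arginine biosynthesis (synthetic toy topology)	C00077	C00327
P_ARG_BIO	Arginine biosynthesis (synthetic toy topology)	C00327	C03406
P_ARG_BIO	Arginine biosynthesis (synthetic toy topology)	C03406	C00062
P_CYS_MET	Cysteine and methionine metabolism (synthetic toy topology)	C00073	C00019
P_CYS_MET	Cysteine and methionine metabolism (synthetic toy topology)	C00019	C00021
P_CYS_MET	Cysteine and methionine metabolism (synthetic toy topology)	C00019	C00170
P_CYS_MET	Cysteine and methionine metabolism (synthetic toy topology)	C00021	C00155
P_CYS_MET	Cysteine and methionine metabolism (synthetic toy topology)	C00021	C00212
P_CYS_MET	Cysteine and methionine metabolism (synthetic toy topology)	C00155	C00073
P_CYS_MET	Cysteine and methionine metabolism (synthetic toy topology)	C00155	C02291
P_CYS_MET	Cysteine and methionine metabolism (synthetic toy topology)	C02291	C00097
P_CYS_MET	Cysteine and methionine metabolism (synthetic toy topology)	C00097	C00491
P_ARG_PRO	Arginine and proline metabolism (synthetic toy topology)	C00062	C00077
P_ARG_PRO	Arginine and proline metabolism (synthetic toy topology)	C00077	C00148
P_ARG_PRO	Arginine and proline metabolism (synthetic toy topology)	C00148	C01157
P_HIS	Histidine metabolism (synthetic toy topology)	C00135	C00388
P_HIS	Histidine metabolism (synthetic toy topology)	C00135	C00386
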