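protein_id	gene_name
SP0001	GENE0001
SP0002	GENE0002
SP0003	GENE0003
SP0004	GENE0004
SP0005	GENE0005
SP0006	GENE0006
SP0007	GENE0007
SP0008	GENE0008
SP0009	GENE0009
SP0010	GENE0010
SP0011	GENE0011
SP0012	GENE0012
SP0013	GENE0013
SP0014	GENE0014
SP0015	GENE0015
SP0016	GENE0016
SP0017	GENE0017
SP0018	GENE0018
SP0019	GENE0019
SP0020	GENE0020
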