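T001	synthetic term 1	GENE0003	GENE0007	GENE0009	GENE0015	GENE0019	GENE0020
T002	synthetic term 2	GENE0007	GENE0008	GENE0014	GENE0017	GENE0018
T003	synthetic term 3	GENE0010	GENE0013	GENE0015
T004	synthetic term 4	GENE0001	GENE0006	GENE0012
T005	synthetic term 5	GENE0006	GENE0011	GENE0013	GENE0014	GENE0015	GENE0016
T006	synthetic term 6	GENE0001	GENE0006	GENE0012
T007	synthetic term 7	GENE0013
T008	synthetic term 8	GENE0010	GENE0013	GENE0015
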