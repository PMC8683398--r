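sample_id	group	gene	ct_target	ct_reference
L1	low	MUC4	22.5099250488525	19.8896723769041
L2	low	MUC4	22.5244272700507	19.7507548014689
L3	low	MUC4	22.0644849793964	19.7937529460841
L4	low	MUC4	22.3246357472418	19.958333805121
L5	low	MUC4	22.4999118597806	20.1390807108182
L6	low	MUC4	22.2047129572332	19.4675085976559
M1	moderate	MUC4	24.9054863294341	19.4133806797604
M2	moderate	MUC4	24.4672806014811	20.5036073185733
M3	moderate	MUC4	25.0207651445686	19.6034860507668
M4	moderate	MUC4	25.0656254439196	20.0867166810242
M5	moderate	MUC4	25.4468980916547	20.4431096724124
M6	moderate	MUC4	24.9836646714583	20.0143647250485
L1	low	SLC26A9	24.2388757196801	19.9074397058932
L2	low	SLC26A9	24.2667793941354	19.9323925248403
L3	low	SLC26A9	23.763028220655	19.9407303137028
L4	low	SLC26A9	24.0877422796318	20.3158056738883
L5	low	SLC26A9	24.1582797690563	19.449467562832
L6	low	SLC26A9	24.1126750818944	19.6053318155721
M1	moderate	SLC26A9	25.4631714228165	19.7445935168157
M2	moderate	SLC26A9	26.4742106892052	20.0617308958932
M3	moderate	SLC26A9	25.6318772421373	20.1606522262471
M4	moderate	SLC26A9	26.0345714575966	19.6991548270047
M5	moderate	SLC26A9	26.7396380445815	21.2148266514064
M6	moderate	SLC26A9	25.5613092342097	19.6540330293546
L1	low	MMP1	32.4699739230455	19.9349940470294
L2	low	MMP1	31.8780514367783	20.2042730295745
L3	low	MMP1	32.1179576083718	19.9676832583608
L4	low	MMP1	32.4642463364402	19.7504864478042
L5	low	MMP1	32.0836275003851	19.8703266725397
L6	low	MMP1	32.0261742203522	19.7596887147832
M1	moderate	MMP1	26.8812770030812	20.1690506370781
M2	moderate	MMP1	27.1567151678566	20.0337748347937
M3	moderate	MMP1	26.9964026366873	20.2668602458334
M4	moderate	MMP1	26.5578637999495	20.0379224765221
M5	moderate	MMP1	27.1055267373598	20.2823306105015
M6	moderate	MMP1	27.1656558323534	20.2934612189959
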