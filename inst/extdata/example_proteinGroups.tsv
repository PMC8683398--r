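Majority protein IDs	Fasta headers	Gene names	Unique peptides	MS/MS count	Potential contaminant	Reverse	Only identified by site	LFQ intensity L01	LFQ intensity L02	LFQ intensity L03	LFQ intensity M01	LFQ intensity M02	LFQ intensity M03
SP0001	sp|SP0001|SYNTH_RABIT synthetic protein 1	GENE0001	2	3				16660383.8	14821149.6	11174347.6	20595736.2	22938001.9	19748646.5
SP0002	sp|SP0002|SYNTH_RABIT synthetic protein 2	GENE0002	3	4				0.0	0.0	9897303.0	11611518.8	0.0	16969296.7
SP0003	sp|SP0003|SYNTH_RABIT synthetic protein 3	GENE0003	4	5	+			288479772.5	0.0	341531283.8	136914366.8	99621619.7	58518071.3
SP0004	sp|SP0004|SYNTH_RABIT synthetic protein 4	GENE0004	5	6				63849401.5	79717150.2	79420700.3	118377809.4	81753190.0	61930881.1
SP0005	sp|SP0005|SYNTH_RABIT synthetic protein 5	GENE0005	0	7				49556512.3	65424268.9	85376937.6	45877936.2	192220348.0	60268701.1
SP0006	sp|SP0006|SYNTH_RABIT synthetic protein 6	GENE0006	2	8				20827617.5	25783465.5	12154867.2	17811081.9	13104816.6	38551494.1
SP0007	sp|SP0007|SYNTH_RABIT synthetic protein 7	GENE0007	3	1				24342477.3	0.0	44551315.9	43681553.5	23213555.1	0.0
SP0008	sp|SP0008|SYNTH_RABIT synthetic protein 8	GENE0008	4	3				50140659.1	41863191.7	42167085.8	26758632.1	19590236.8	21535424.4
SP0009	sp|SP0009|SYNTH_RABIT synthetic protein 9	GENE0009	5	4				10036188.7	0.0	0.0	52893888.8	36712817.1	32766545.2
SP0010	sp|SP0010|SYNTH_RABIT synthetic protein 10	GENE0010	1	5				115957210.9	130699497.2	115744887.8	165477947.0	158493102.1	137050842.9
SP0011	sp|SP0011|SYNTH_RABIT synthetic protein 11	GENE0011	2	6				2755243.1	0.0	2883906.9	0.0	2735608.3	3583111.0
SP0012	sp|SP0012|SYNTH_RABIT synthetic protein 12	GENE0012	3	7				73367856.9	87690715.4	65647061.4	30516829.3	0.0	23402450.9
SP0013	sp|SP0013|SYNTH_RABIT synthetic protein 13	GENE0013	4	8				36595143.8	29562645.4	35780011.1	0.0	29788611.2	28321049.8
SP0014	sp|SP0014|SYNTH_RABIT synthetic protein 14	GENE0014	5	2				328948210.0	280641872.4	231242915.0	89566580.9	69745016.3	124615918.7
SP0015	sp|SP0015|SYNTH_RABIT synthetic protein 15	GENE0015	1	3				73398726.4	114125198.5	140726603.5	96402340.2	135637629.9	112645704.9
SP0016	sp|SP0016|SYNTH_RABIT synthetic protein 16	GENE0016	2	4				87963182.2	42997907.4	61893668.0	108468313.1	71198575.7	71033478.7
SP0017	sp|SP0017|SYNTH_RABIT synthetic protein 17	GENE0017	3	5				26121423.1	27672115.4	19868890.2	16683501.6	27575146.3	0.0
SP0018	sp|SP0018|SYNTH_RABIT synthetic protein 18	GENE0018	4	6				78184857.1	0.0	112157080.2	83680088.0	67040023.2	75140039.1
SP0019	sp|SP0019|SYNTH_RABIT synthetic protein 19	GENE0019	5	7				0.0	20415159.2	36430669.7	64396640.4	63975290.9	28804433.7
SP0020	sp|SP0020|SYNTH_RABIT synthetic protein 20	GENE0020	1	8				13161956.9	0.0	14545582.7	10666694.3	0.0	9307196.3
SP0021	sp|SP0021|SYNTH_RABIT synthetic protein 21	GENE0021	2	2				21898799.6	0.0	21507766.4	40239865.7	35185062.4	67731380.4
SP0022	sp|SP0022|SYNTH_RABIT synthetic protein 22	GENE0022	3	3				75848808.3	104600804.8	0.0	114760880.0	145608386.5	61256585.0
SP0023	sp|SP0023|SYNTH_RABIT synthetic protein 23	GENE0023	4	4				6321646.9	0.0	8199633.1	7172064.7	0.0	5383147.8
SP0024	sp|SP0024|SYNTH_RABIT synthetic protein 24	GENE0024	5	5				24138863.7	23347418.2	21413322.9	14955062.5	22584314.1	25258057.5
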