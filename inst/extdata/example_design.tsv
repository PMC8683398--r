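sample_id	group	cohort	experiment
L01	low	D	comprehensive
L02	low	D	comprehensive
L03	low	D	comprehensive
M01	moderate	D	comprehensive
M02	moderate	D	comprehensive
M03	moderate	D	comprehensive
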