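sample_id	treatment	n_reads	richness	hill1	hill2	faith	evenness
SymLPul1	SymL	12437	38	3.76	2.39	0.333	0.364
SymLPul2	SymL	13394	39	3.49	2.26	0.367	0.341
SymLPul3	SymL	11826	27	3.43	2.26	0.184	0.374
SymLPul4	SymL	16425	29	3.27	2.17	0.206	0.352
SymLPul5	SymL	13997	39	3.51	2.29	0.255	0.343
SymDPul1	SymD	13346	37	3.45	2.26	0.255	0.342
SymDPul2	SymD	17415	42	3.45	2.24	0.260	0.331
SymDPul3	SymD	13342	32	3.41	2.29	0.208	0.353
SymDPul4	SymD	14175	37	3.46	2.22	0.224	0.343
SymDPul5	SymD	15073	28	3.26	2.22	0.174	0.354
ApoLPul1	ApoL	15829	53	3.95	2.25	0.336	0.345
ApoLPul2	ApoL	17442	58	4.09	2.26	0.292	0.347
ApoLPul3	ApoL	14280	140	10.23	3.02	0.618	0.470
ApoLPul4	ApoL	12120	25	3.12	2.14	0.267	0.353
ApoLPul5	ApoL	19938	69	4.45	2.26	0.358	0.352
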