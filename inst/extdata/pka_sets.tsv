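group	sillero	bjellqvist	emboss	ipc_peptide
Nterm	8.2	7.5	8.6	9.564
Cterm	3.2	3.55	3.6	2.383
D	4.0	4.05	3.9	3.887
E	4.5	4.45	4.1	4.317
C	9.0	9.0	8.5	8.297
Y	10.0	10.0	10.1	10.071
H	6.4	5.98	6.5	5.492
K	10.4	10.0	10.8	10.189
R	12.0	12.0	12.5	11.84
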