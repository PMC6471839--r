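source	annotation	spectral_counts	unique_peptide_sequences	metaclusters
Bacterial	With useful annotation	32469	10675	1033
Bacterial	Without useful annotation	8455	3541	889
Human	With useful annotation	8951	1034	212
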