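type	trna	sequence	note
Q	Gln	TGGCGCCCAACGTGGGGC	synthetic stand-in default; replace with curated tRNA-Gln PBS
P	Pro	TGGGGGCTCGTCCGGGAT	canonical MoMLV tRNA-Pro PBS
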