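# H+-coupling signature residue set, Glt_Ph numbering
ref_position	allowed_residues
92	ALIVMF
311	L
405	N
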