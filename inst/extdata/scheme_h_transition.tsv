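# Transition variant of the H+-coupling signature (substitutions relative to
# the Na+-coupled reference): [T/S]92 -> [A/L/I/V/M/F], M311L, D405N
ref_position	allowed_residues
92	ALIVMF
311	L
405	N
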