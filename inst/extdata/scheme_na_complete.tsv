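# Full Na+-binding site residue set, Glt_Ph numbering
ref_position	allowed_residues
92	ST
93	ST
310	N
311	MS
312	DE
405	DE
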