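oligomer,count
monomers,11
dimers,16
tetramers,3
hexamers,2
octamers,1
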