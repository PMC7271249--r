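source_entrez	target_entrez	effect
58231	50523	activation
50523	22601	inhibition
50523	97064	inhibition
22601	21679	activation
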