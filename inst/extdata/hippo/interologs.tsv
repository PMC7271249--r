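entrez_a	entrez_b	taxa
58231	64010	9606
50523	58231	9606
50523	64010	9606
22601	50523	9606
50523	97064	9606
21679	22601	9606
21679	97064	9606
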