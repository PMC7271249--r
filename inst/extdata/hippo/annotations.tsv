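entrez	term
58231	T00003
64010	T00003
50523	T00003
22601	T00003
97064	T00003
21679	T00003
58231	T00002
50523	T00002
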