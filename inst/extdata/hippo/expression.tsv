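gene	trophoblast	stem cell
58231	25	24
64010	18	17
50523	30	28
22601	40	38
97064	12	11
21679	22	0.2
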