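child	parent	relation
T00002	T00001	is_a
T00003	T00001	is_a
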