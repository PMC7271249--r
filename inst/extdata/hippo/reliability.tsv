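mi_code	name	reliability
MI:0077	nuclear magnetic resonance	10
MI:0067	light scattering	10
MI:0018	two hybrid	5
MI:0019	coimmunoprecipitation	5
MI:0428	imaging technique (microscopy)	1
MI:1060	rnai-based approach	1
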