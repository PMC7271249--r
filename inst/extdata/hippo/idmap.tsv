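provider_id	entrez	symbol	mgi	uniprot
uniprotkb:P90001	58231	Stk4	MGI:1000001	P90001
uniprotkb:P90002	64010	Sav1	MGI:1000002	P90002
uniprotkb:P90003	50523	Lats2	MGI:1000003	P90003
uniprotkb:P90004	22601	Yap1	MGI:1000004	P90004
uniprotkb:P90005	97064	Wwtr1	MGI:1000005	P90005
uniprotkb:P90006	21679	Tead4	MGI:1000006	P90006
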