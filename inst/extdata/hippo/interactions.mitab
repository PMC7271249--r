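#ID(s) interactor A	ID(s) interactor B	Alt. ID(s) A	Alt. ID(s) B	Alias(es) A	Alias(es) B	Interaction detection method(s)	Publication 1st author(s)	Publication Identifier(s)	Taxid A	Taxid B	Interaction type(s)	Source database(s)	Interaction identifier(s)	Confidence value(s)
uniprotkb:P90001	uniprotkb:P90002	-	-	-	-	psi-mi:"MI:0018"(two hybrid)	-	pubmed:8000001	taxid:10090(mouse)	taxid:10090(mouse)	psi-mi:"MI:0915"(physical association)	synthetic-provider	-	-
uniprotkb:P90001	uniprotkb:P90002	-	-	-	-	psi-mi:"MI:0019"(coimmunoprecipitation)	-	pubmed:8000002	taxid:10090(mouse)	taxid:10090(mouse)	psi-mi:"MI:0915"(physical association)	synthetic-provider	-	-
uniprotkb:P90001	uniprotkb:P90002	-	-	-	-	psi-mi:"MI:0018"(two hybrid)	-	pubmed:8000003	taxid:10090(mouse)	taxid:10090(mouse)	psi-mi:"MI:0915"(physical association)	synthetic-provider	-	-
uniprotkb:P90001	uniprotkb:P90003	-	-	-	-	psi-mi:"MI:0018"(two hybrid)	-	pubmed:8000004	taxid:10090(mouse)	taxid:10090(mouse)	psi-mi:"MI:0915"(physical association)	synthetic-provider	-	-
uniprotkb:P90001	uniprotkb:P90003	-	-	-	-	psi-mi:"MI:0019"(coimmunoprecipitation)	-	pubmed:8000005	taxid:10090(mouse)	taxid:10090(mouse)	psi-mi:"MI:0915"(physical association)	synthetic-provider	-	-
uniprotkb:P90001	uniprotkb:P90003	-	-	-	-	psi-mi:"MI:0018"(two hybrid)	-	pubmed:8000006	taxid:10090(mouse)	taxid:10090(mouse)	psi-mi:"MI:0915"(physical association)	synthetic-provider	-	-
uniprotkb:P90002	uniprotkb:P90003	-	-	-	-	psi-mi:"MI:0018"(two hybrid)	-	pubmed:8000007	taxid:10090(mouse)	taxid:10090(mouse)	psi-mi:"MI:0915"(physical association)	synthetic-provider	-	-
uniprotkb:P90002	uniprotkb:P90003	-	-	-	-	psi-mi:"MI:0019"(coimmunoprecipitation)	-	pubmed:8000008	taxid:10090(mouse)	taxid:10090(mouse)	psi-mi:"MI:0915"(physical association)	synthetic-provider	-	-
uniprotkb:P90002	uniprotkb:P90003	-	-	-	-	psi-mi:"MI:0018"(two hybrid)	-	pubmed:8000009	taxid:10090(mouse)	taxid:10090(mouse)	psi-mi:"MI:0915"(physical association)	synthetic-provider	-	-
uniprotkb:P90003	uniprotkb:P90004	-	-	-	-	psi-mi:"MI:0018"(two hybrid)	-	pubmed:8000010	taxid:10090(mouse)	taxid:10090(mouse)	psi-mi:"MI:0915"(physical association)	synthetic-provider	-	-
uniprotkb:P90003	uniprotkb:P90004	-	-	-	-	psi-mi:"MI:0019"(coimmunoprecipitation)	-	pubmed:8000011	taxid:10090(mouse)	taxid:10090(mouse)	psi-mi:"MI:0915"(physical association)	synthetic-provider	-	-
uniprotkb:P90003	uniprotkb:P90004	-	-	-	-	psi-mi:"MI:0018"(two hybrid)	-	pubmed:8000012	taxid:10090(mouse)	taxid:10090(mouse)	psi-mi:"MI:0915"(physical association)	synthetic-provider	-	-
uniprotkb:P90003	uniprotkb:P90005	-	-	-	-	psi-mi:"MI:0018"(two hybrid)	-	pubmed:8000013	taxid:10090(mouse)	taxid:10090(mouse)	psi-mi:"MI:0915"(physical association)	synthetic-provider	-	-
uniprotkb:P90003	uniprotkb:P90005	-	-	-	-	psi-mi:"MI:0019"(coimmunoprecipitation)	-	pubmed:8000014	taxid:10090(mouse)	taxid:10090(mouse)	psi-mi:"MI:0915"(physical association)	synthetic-provider	-	-
uniprotkb:P90003	uniprotkb:P90005	-	-	-	-	psi-mi:"MI:0018"(two hybrid)	-	pubmed:8000015	taxid:10090(mouse)	taxid:10090(mouse)	psi-mi:"MI:0915"(physical association)	synthetic-provider	-	-
uniprotkb:P90004	uniprotkb:P90006	-	-	-	-	psi-mi:"MI:0018"(two hybrid)	-	pubmed:8000016	taxid:10090(mouse)	taxid:10090(mouse)	psi-mi:"MI:0915"(physical association)	synthetic-provider	-	-
uniprotkb:P90004	uniprotkb:P90006	-	-	-	-	psi-mi:"MI:0019"(coimmunoprecipitation)	-	pubmed:8000017	taxid:10090(mouse)	taxid:10090(mouse)	psi-mi:"MI:0915"(physical association)	synthetic-provider	-	-
uniprotkb:P90004	uniprotkb:P90006	-	-	-	-	psi-mi:"MI:0018"(two hybrid)	-	pubmed:8000018	taxid:10090(mouse)	taxid:10090(mouse)	psi-mi:"MI:0915"(physical association)	synthetic-provider	-	-
uniprotkb:P90005	uniprotkb:P90006	-	-	-	-	psi-mi:"MI:0018"(two hybrid)	-	pubmed:8000019	taxid:10090(mouse)	taxid:10090(mouse)	psi-mi:"MI:0915"(physical association)	synthetic-provider	-	-
uniprotkb:P90005	uniprotkb:P90006	-	-	-	-	psi-mi:"MI:0019"(coimmunoprecipitation)	-	pubmed:8000020	taxid:10090(mouse)	taxid:10090(mouse)	psi-mi:"MI:0915"(physical association)	synthetic-provider	-	-
uniprotkb:P90005	uniprotkb:P90006	-	-	-	-	psi-mi:"MI:0018"(two hybrid)	-	pubmed:8000021	taxid:10090(mouse)	taxid:10090(mouse)	psi-mi:"MI:0915"(physical association)	synthetic-provider	-	-
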