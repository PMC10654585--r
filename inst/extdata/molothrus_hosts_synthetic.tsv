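id	species	source	locality
MB001	Molothrus bonariensis	wild_capture	NA
MB002	Molothrus bonariensis	wild_capture	NA
MB003	Molothrus bonariensis	wild_capture	NA
MB004	Molothrus bonariensis	wild_capture	NA
MB005	Molothrus bonariensis	wild_capture	NA
MB006	Molothrus bonariensis	wild_capture	NA
MB007	Molothrus bonariensis	wild_capture	NA
MB008	Molothrus bonariensis	wild_capture	NA
MB009	Molothrus bonariensis	wild_capture	NA
MB010	Molothrus bonariensis	wild_capture	NA
MB011	Molothrus bonariensis	wild_capture	NA
MB012	Molothrus bonariensis	wild_capture	NA
MB013	Molothrus bonariensis	wild_capture	NA
MB014	Molothrus bonariensis	wild_capture	NA
MB015	Molothrus bonariensis	wild_capture	NA
MB016	Molothrus bonariensis	wild_capture	NA
MB017	Molothrus bonariensis	wild_capture	NA
MB018	Molothrus bonariensis	wild_capture	NA
MB019	Molothrus bonariensis	wild_capture	NA
MB020	Molothrus bonariensis	wild_capture	NA
MB021	Molothrus bonariensis	wild_capture	NA
MB022	Molothrus bonariensis	wild_capture	NA
MB023	Molothrus bonariensis	roadkill	NA
MB024	Molothrus bonariensis	roadkill	NA
MB025	Molothrus bonariensis	roadkill	NA
MB026	Molothrus bonariensis	roadkill	NA
MB027	Molothrus bonariensis	roadkill	NA
MB028	Molothrus bonariensis	roadkill	NA
MB029	Molothrus bonariensis	roadkill	NA
MB030	Molothrus bonariensis	roadkill	NA
MB031	Molothrus bonariensis	roadkill	NA
MB032	Molothrus bonariensis	roadkill	NA
MB033	Molothrus bonariensis	museum_skin	NA
MB034	Molothrus bonariensis	museum_skin	NA
MB035	Molothrus bonariensis	museum_skin	NA
MB036	Molothrus bonariensis	museum_skin	NA
MB037	Molothrus bonariensis	museum_skin	NA
MB038	Molothrus bonariensis	museum_skin	NA
MB039	Molothrus bonariensis	museum_skin	NA
MB040	Molothrus bonariensis	museum_skin	NA
MB041	Molothrus bonariensis	museum_skin	NA
MB042	Molothrus bonariensis	museum_skin	NA
MB043	Molothrus bonariensis	museum_skin	NA
MB044	Molothrus bonariensis	museum_skin	NA
MB045	Molothrus bonariensis	museum_skin	NA
MB046	Molothrus bonariensis	museum_skin	NA
MB047	Molothrus bonariensis	museum_skin	NA
MB048	Molothrus bonariensis	museum_skin	NA
MB049	Molothrus bonariensis	museum_skin	NA
MB050	Molothrus bonariensis	museum_skin	NA
MB051	Molothrus bonariensis	museum_skin	NA
MB052	Molothrus bonariensis	museum_skin	NA
MB053	Molothrus bonariensis	museum_skin	NA
MB054	Molothrus bonariensis	museum_skin	NA
MB055	Molothrus bonariensis	museum_skin	NA
MB056	Molothrus bonariensis	museum_skin	NA
MB057	Molothrus bonariensis	museum_skin	NA
MB058	Molothrus bonariensis	museum_skin	NA
MB059	Molothrus bonariensis	museum_skin	NA
MB060	Molothrus bonariensis	museum_skin	NA
MB061	Molothrus bonariensis	museum_skin	NA
MB062	Molothrus bonariensis	museum_skin	NA
MB063	Molothrus bonariensis	museum_skin	NA
MB064	Molothrus bonariensis	museum_skin	NA
MB065	Molothrus bonariensis	museum_skin	NA
MB066	Molothrus bonariensis	museum_skin	NA
MB067	Molothrus bonariensis	museum_skin	NA
MB068	Molothrus bonariensis	museum_skin	NA
MB069	Molothrus bonariensis	museum_skin	NA
MB070	Molothrus bonariensis	museum_skin	NA
MB071	Molothrus bonariensis	museum_skin	NA
MB072	Molothrus bonariensis	museum_skin	NA
MB073	Molothrus bonariensis	museum_skin	NA
MB074	Molothrus bonariensis	museum_skin	NA
MB075	Molothrus bonariensis	museum_skin	NA
MB076	Molothrus bonariensis	museum_skin	NA
MB077	Molothrus bonariensis	museum_skin	NA
MB078	Molothrus bonariensis	museum_skin	NA
MB079	Molothrus bonariensis	museum_skin	NA
MB080	Molothrus bonariensis	museum_skin	NA
MB081	Molothrus bonariensis	museum_skin	NA
MB082	Molothrus bonariensis	museum_skin	NA
MB083	Molothrus bonariensis	museum_skin	NA
MB084	Molothrus bonariensis	museum_skin	NA
MB085	Molothrus bonariensis	museum_skin	NA
MB086	Molothrus bonariensis	museum_skin	NA
MB087	Molothrus bonariensis	museum_skin	NA
MB088	Molothrus bonariensis	museum_skin	NA
MB089	Molothrus bonariensis	museum_skin	NA
MB090	Molothrus bonariensis	museum_skin	NA
MB091	Molothrus bonariensis	museum_skin	NA
MB092	Molothrus bonariensis	museum_skin	NA
MB093	Molothrus bonariensis	museum_skin	NA
MB094	Molothrus bonariensis	museum_skin	NA
MB095	Molothrus bonariensis	museum_skin	NA
MB096	Molothrus bonariensis	museum_skin	NA
MB097	Molothrus bonariensis	museum_skin	NA
MB098	Molothrus bonariensis	museum_skin	NA
MB099	Molothrus bonariensis	museum_skin	NA
MB100	Molothrus bonariensis	museum_skin	NA
MB101	Molothrus bonariensis	museum_skin	NA
MB102	Molothrus bonariensis	museum_skin	NA
MB103	Molothrus bonariensis	museum_skin	NA
MB104	Molothrus bonariensis	museum_skin	NA
MB105	Molothrus bonariensis	museum_skin	NA
MB106	Molothrus bonariensis	museum_skin	NA
MB107	Molothrus bonariensis	museum_skin	NA
MB108	Molothrus bonariensis	museum_skin	NA
MB109	Molothrus bonariensis	museum_skin	NA
MB110	Molothrus bonariensis	museum_skin	NA
MB111	Molothrus bonariensis	museum_skin	NA
MB112	Molothrus bonariensis	museum_skin	NA
MB113	Molothrus bonariensis	museum_skin	NA
MB114	Molothrus bonariensis	museum_skin	NA
MB115	Molothrus bonariensis	museum_skin	NA
MB116	Molothrus bonariensis	museum_skin	NA
MB117	Molothrus bonariensis	museum_skin	NA
MB118	Molothrus bonariensis	museum_skin	NA
MB119	Molothrus bonariensis	museum_skin	NA
MB120	Molothrus bonariensis	museum_skin	NA
MB121	Molothrus bonariensis	museum_skin	NA
MB122	Molothrus bonariensis	museum_skin	NA
MB123	Molothrus bonariensis	museum_skin	NA
MB124	Molothrus bonariensis	museum_skin	NA
MB125	Molothrus bonariensis	museum_skin	NA
MB126	Molothrus bonariensis	museum_skin	NA
MB127	Molothrus bonariensis	museum_skin	NA
MB128	Molothrus bonariensis	museum_skin	NA
MB129	Molothrus bonariensis	museum_skin	NA
MB130	Molothrus bonariensis	museum_skin	NA
MB131	Molothrus bonariensis	museum_skin	NA
MB132	Molothrus bonariensis	museum_skin	NA
MB133	Molothrus bonariensis	museum_skin	NA
MB134	Molothrus bonariensis	museum_skin	NA
MB135	Molothrus bonariensis	museum_skin	NA
MB136	Molothrus bonariensis	museum_skin	NA
MB137	Molothrus bonariensis	museum_skin	NA
MB138	Molothrus bonariensis	museum_skin	NA
MB139	Molothrus bonariensis	museum_skin	NA
MB140	Molothrus bonariensis	museum_skin	NA
MB141	Molothrus bonariensis	museum_skin	NA
MB142	Molothrus bonariensis	museum_skin	NA
MB143	Molothrus bonariensis	museum_skin	NA
MB144	Molothrus bonariensis	museum_skin	NA
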