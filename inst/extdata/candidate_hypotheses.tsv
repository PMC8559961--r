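hypothesis	gene_id	gene_class	unplaced	passed_filter
H1	CYP325T2	CYP	FALSE	FALSE
H1	CYP9J24	CYP	FALSE	FALSE
H2	CYP6AA6	CYP	FALSE	FALSE
H2	CYP6BB2	CYP	FALSE	FALSE
H2	CYP9AE1	CYP	FALSE	TRUE
H2	CYP9J10	CYP	FALSE	FALSE
H2	CYP9J17	CYP	FALSE	FALSE
H2	CYP9J26	CYP	FALSE	FALSE
H2	CYP9J27	CYP	FALSE	FALSE
H2	CYP9J28	CYP	FALSE	FALSE
H2	CYP9M5	CYP	FALSE	FALSE
H2	CYP9M6	CYP	FALSE	FALSE
H3	CYP6AA6	CYP	FALSE	TRUE
H3	CYP6BB2	CYP	FALSE	TRUE
H3	CYP9AE1	CYP	FALSE	TRUE
H3	CYP9J10	CYP	FALSE	TRUE
H3	CYP9J17	CYP	FALSE	TRUE
H3	CYP9J26	CYP	FALSE	TRUE
H3	CYP9J27	CYP	FALSE	TRUE
H3	CYP9J28	CYP	FALSE	TRUE
H3	CYP9M5	CYP	FALSE	TRUE
H3	CYP9M6	CYP	FALSE	TRUE
H4	AAEL005602	TF	FALSE	TRUE
H4	AAEL006032	TF	FALSE	TRUE
H4	AAEL006035	TF	FALSE	TRUE
H4	AAEL006597	TF	FALSE	TRUE
H4	AAEL007988	TF	FALSE	FALSE
H4	AAEL010576	TF	FALSE	TRUE
H4	AAEL013562	TF	FALSE	FALSE
H4	AAEL013760	TF	FALSE	TRUE
H4	AAEL018695	TF	FALSE	TRUE
H4	AAEL019560	TF	FALSE	TRUE
H4	AAEL019840	TF	FALSE	TRUE
H4	AAEL021303	TF	FALSE	TRUE
H4	AAEL021877	TF	FALSE	TRUE
H4	AAEL022135	TF	FALSE	FALSE
H4	AAEL022195	TF	FALSE	TRUE
H4	AAEL023574	TF	FALSE	TRUE
H4	AAEL023842	TF	TRUE	TRUE
H4	AAEL025336	TF	TRUE	TRUE
H4	AAEL026672	TF	FALSE	TRUE
H4	AAEL026933	TF	FALSE	TRUE
H4	AAEL028025	TF	FALSE	TRUE
H4	AAEL028112	TF	FALSE	TRUE
H4	AAEL028157	TF	FALSE	FALSE
H5	AAEL001459	TF	FALSE	TRUE
H5	AAEL002896	TF	FALSE	TRUE
H5	AAEL003176	TF	FALSE	TRUE
H5	AAEL003506	TF	FALSE	TRUE
H5	AAEL004130	TF	FALSE	FALSE
H5	AAEL004669	TF	FALSE	FALSE
H5	AAEL005247	TF	FALSE	TRUE
H5	AAEL005602	TF	FALSE	TRUE
H5	AAEL005606	TF	FALSE	TRUE
H5	AAEL006197	TF	FALSE	TRUE
H5	AAEL006206	lncRNA	FALSE	FALSE
H5	AAEL006932	TF	FALSE	FALSE
H5	AAEL007970	lncRNA	FALSE	FALSE
H5	AAEL008401	TF	FALSE	TRUE
H5	AAEL011160	TF	FALSE	FALSE
H5	AAEL012628	TF	FALSE	FALSE
H5	AAEL012990	TF	FALSE	FALSE
H5	AAEL014406	TF	FALSE	TRUE
H5	AAEL019765	TF	FALSE	FALSE
H5	AAEL019809	TF	FALSE	TRUE
H5	AAEL019968	TF	FALSE	TRUE
H5	AAEL020179	lncRNA	TRUE	TRUE
H5	AAEL020308	lncRNA	FALSE	FALSE
H5	AAEL020350	lncRNA	FALSE	TRUE
H5	AAEL020445	lncRNA	FALSE	FALSE
H5	AAEL020459	TF	FALSE	TRUE
H5	AAEL020507	lncRNA	FALSE	FALSE
H5	AAEL020816	lncRNA	FALSE	TRUE
H5	AAEL020844	lncRNA	FALSE	FALSE
H5	AAEL021107	lncRNA	FALSE	FALSE
H5	AAEL021117	lncRNA	FALSE	TRUE
H5	AAEL021124	lncRNA	FALSE	FALSE
H5	AAEL021188	lncRNA	FALSE	FALSE
H5	AAEL021207	lncRNA	FALSE	FALSE
H5	AAEL021235	TF	FALSE	TRUE
H5	AAEL021303	TF	FALSE	TRUE
H5	AAEL021326	lncRNA	FALSE	FALSE
H5	AAEL021614	lncRNA	FALSE	TRUE
H5	AAEL021658	lncRNA	FALSE	TRUE
H5	AAEL021758	lncRNA	TRUE	TRUE
H5	AAEL021796	lncRNA	FALSE	TRUE
H5	AAEL021901	lncRNA	FALSE	TRUE
H5	AAEL021935	lncRNA	FALSE	FALSE
H5	AAEL021952	TF	FALSE	TRUE
H5	AAEL021984	lncRNA	FALSE	FALSE
H5	AAEL022024	lncRNA	FALSE	FALSE
H5	AAEL022110	lncRNA	FALSE	FALSE
H5	AAEL022402	TF	FALSE	FALSE
H5	AAEL022278	lncRNA	TRUE	TRUE
H5	AAEL022636	lncRNA	FALSE	FALSE
H5	AAEL022706	lncRNA	FALSE	TRUE
H5	AAEL022711	lncRNA	FALSE	TRUE
H5	AAEL023156	lncRNA	FALSE	TRUE
H5	AAEL023170	lncRNA	FALSE	FALSE
H5	AAEL023172	lncRNA	FALSE	FALSE
H5	AAEL023265	TF	FALSE	TRUE
H5	AAEL023302	lncRNA	FALSE	FALSE
H5	AAEL023306	lncRNA	FALSE	TRUE
H5	AAEL023405	lncRNA	FALSE	FALSE
H5	AAEL023428	lncRNA	FALSE	FALSE
H5	AAEL023707	lncRNA	FALSE	FALSE
H5	AAEL023795	lncRNA	TRUE	TRUE
H5	AAEL023937	lncRNA	FALSE	FALSE
H5	AAEL024060	lncRNA	FALSE	FALSE
H5	AAEL024161	lncRNA	FALSE	FALSE
H5	AAEL024318	lncRNA	FALSE	FALSE
H5	AAEL024523	lncRNA	TRUE	TRUE
H5	AAEL024603	lncRNA	FALSE	TRUE
H5	AAEL024640	lncRNA	FALSE	TRUE
H5	AAEL024782	lncRNA	FALSE	TRUE
H5	AAEL024864	lncRNA	FALSE	TRUE
H5	AAEL024869	lncRNA	FALSE	TRUE
H5	AAEL024872	lncRNA	FALSE	FALSE
H5	AAEL024949	lncRNA	FALSE	FALSE
H5	AAEL024959	lncRNA	FALSE	FALSE
H5	AAEL025193	lncRNA	FALSE	FALSE
H5	AAEL025264	lncRNA	FALSE	FALSE
H5	AAEL025399	lncRNA	FALSE	FALSE
H5	AAEL025559	lncRNA	FALSE	FALSE
H5	AAEL025618	lncRNA	FALSE	TRUE
H5	AAEL025640	lncRNA	TRUE	TRUE
H5	AAEL025853	lncRNA	FALSE	FALSE
H5	AAEL025854	lncRNA	FALSE	FALSE
H5	AAEL025912	lncRNA	FALSE	FALSE
H5	AAEL026107	lncRNA	FALSE	TRUE
H5	AAEL026208	lncRNA	FALSE	FALSE
H5	AAEL026242	lncRNA	FALSE	TRUE
H5	AAEL026527	lncRNA	FALSE	TRUE
H5	AAEL026574	TF	FALSE	TRUE
H5	AAEL026769	lncRNA	FALSE	FALSE
H5	AAEL026784	lncRNA	FALSE	TRUE
H5	AAEL026801	lncRNA	FALSE	FALSE
H5	AAEL026917	TF	FALSE	FALSE
H5	AAEL027182	lncRNA	FALSE	FALSE
H5	AAEL027227	lncRNA	FALSE	TRUE
H5	AAEL027357	lncRNA	FALSE	TRUE
H5	AAEL027461	lncRNA	FALSE	TRUE
H5	AAEL027939	lncRNA	FALSE	FALSE
H5	AAEL027946	lncRNA	FALSE	FALSE
H5	AAEL028219	lncRNA	FALSE	FALSE
H5	AAEL028241	lncRNA	FALSE	FALSE
H6	CYP6CB1	CYP	FALSE	TRUE
H6	CYP9J18	CYP	FALSE	TRUE
H6	CYP9J19	CYP	FALSE	TRUE
H6	CYP9J2	CYP	FALSE	TRUE
H6	CYP9J22	CYP	FALSE	TRUE
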