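genotype_id	term_id	ontology	qualifier	reference
MGI:5502689	MP:9700001	phenotype		J:000001
MGI:3836994	MP:9700002	phenotype		J:000002
MGI:5571091	MP:9700003	phenotype		J:000003
MGI:4429149	MP:9700004	phenotype		J:000004
MGI:4430413	MP:0003059	phenotype		J:000005
MGI:4430413	OMIM:606176	disease		J:000006
MGI:5514345	OMIM:152700	disease		J:000007
MGI:3689403	MP:0002081	phenotype		J:000008
syn:gt-rosa-viral	MP:9700005	phenotype		J:000009
syn:gt-col1a1-flox	MP:9700006	phenotype		J:000010
syn:gt-hprt-cargo	MP:9700007	phenotype		J:000011
MGI:4412090	MP:9700008	phenotype		J:000012
syn:gt-syng1-tyr	MP:9700009	phenotype		J:000013
MGI:4356019	MP:9700010	phenotype		J:000014
MGI:3039435	OMIM:222100	disease		J:000015
MGI:5544092	MP:9700011	phenotype		J:000016
syn:gt-tgtyrhras	MP:9700012	phenotype		J:000017
syn:gt-syng2-self	MP:9700013	phenotype		J:000018
syn:gt-ctnnb1	MP:9700014	phenotype		J:000019
syn:gt-app	MP:9700015	phenotype		J:000020
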