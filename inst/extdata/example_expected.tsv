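genotype_id	label	terminal_box	annotate_markers	exclusion_reason
MGI:5502689	tetO-Notch4* transgene + Tek-tTA transactivator	B8_TRANSGENE_PLUS_GENE	syn:Notch4;syn:TgNotch4	NA
MGI:3836994	Prnp knock-out + Prnp* transgene	B9_TRANSGENE_ENDOGENOUS_MATCH	syn:Prnp;syn:TgPrnp	NA
MGI:5571091	39-gene deletion + EGFP reporter transgene	B4_MULTIGENIC_MARKER	syn:Del7	NA
MGI:4429149	Ewsr1 knock-in of human FLI1, conditional	EXCLUDED		non_mouse_expressed
MGI:4430413	Kcnj11* knock-in at Rosa26 + Ins2-cre, conditional	B10_DOCKING_SITE	syn:Kcnj11	NA
MGI:5514345	Apoe;Fasl double homozygote	EXCLUDED		multi_marker_no_expressed
MGI:3689403	Smo floxed + Isl1 knock-in cre, conditional	B3_SINGLE_AFTER_FILTER	syn:Smo	NA
syn:gt-rosa-viral	Rosa26 knock-in with viral-only cargo	EXCLUDED		rosa_suppressed
syn:gt-col1a1-flox	floxed Col1a1 + CAG-cre, conditional	B3_SINGLE_AFTER_FILTER	MGI:88467	NA
syn:gt-hprt-cargo	Hprt docking-site knock-in with mouse cargo	B10_DOCKING_SITE	syn:Syng3	NA
MGI:4412090	Foxg1 knock-in tTA + tetO-Gsx2 transgene	EXCLUDED		unresolved_multi
syn:gt-syng1-tyr	knock-in using Tyr as coat-colour reporter	EXCLUDED		unresolved_multi
MGI:4356019	Epn1;Epn2 digenic double homozygote	EXCLUDED		multi_marker_no_expressed
MGI:3039435	Sell knock-out on NOD background	B1_SINGLE	syn:Sell	NA
MGI:5544092	Edn2 insertion at the Igs1 intergenic site	EXCLUDED		unresolved_multi
syn:gt-tgtyrhras	cre transgene with Hras1+Trap1a cargo, conditional	B6_TRANSGENE_ONLY	syn:TgTyrHras	NA
syn:gt-syng2-self	conditional knock-in expressing its own gene	B11_SELF_EXPRESSED	syn:Syng2	NA
syn:gt-ctnnb1	Ctnnb1 knock-in expressing Nfkbia	EXCLUDED		unresolved_multi
syn:gt-app	App knock-out homozygote	B1_SINGLE	syn:App	NA
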