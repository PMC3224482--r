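source	relation	target	causal_flag	species	tissue	pmids	blocks
taof(Nfe2l2)	increases	r(Nqo1)	causal	mouse	lung	11035812	source:oxidative
taof(Nfe2l2)	increases	r(Hmox1)	causal	mouse	lung	10473555	source:oxidative
taof(Nfe2l2)	increases	r(Gclc)	causal	human	bronchial epithelium	12234984	source:oxidative
taof(Nfe2l2)	increases	r(Gclm)	causal	human	bronchial epithelium	12234984	source:oxidative
taof(Nfe2l2)	increases	r(Prdx1)	causal	mouse	lung	12059788	source:oxidative
taof(Nfe2l2)	increases	r(Txnrd1)	causal	rat	liver	12713573	source:oxidative
p(Keap1)	decreases	r(Nqo1)	causal	mouse	lung	12682069	source:oxidative
p(Keap1)	decreases	r(Hmox1)	causal	mouse	lung	12682069	source:oxidative
p(Keap1)	decreases	r(Gclc)	causal	mouse	fibroblast	12682069	source:oxidative
p(Keap1)	decreases	r(Gclm)	causal	mouse	fibroblast	12682069	source:oxidative
taof(Ahr)	increases	r(Cyp1a1)	causal	human	liver	8631989	source:xenobiotic
taof(Ahr)	increases	r(Cyp1b1)	causal	human	liver	8631989	source:xenobiotic
taof(Ahr)	increases	r(Nqo1)	causal	rat	liver	10620279	source:xenobiotic
taof(Ahr)	increases	r(Ahrr)	causal	mouse	lung	10325245	source:xenobiotic
taof(Atf6)	increases	r(Hspa5)	causal	human	kidney	10564271	source:ER
taof(Atf6)	increases	r(Ddit3)	causal	human	kidney	10564271	source:ER
taof(Atf6)	increases	r(Xbp1)	causal	human	HeLa	11779464	source:ER
taof(Atf6)	increases	r(Herpud1)	causal	human	HeLa	11779464	source:ER
taof(Hif1a)	increases	r(Vegfa)	causal	human	coronary artery endothelium	8756616	source:hypoxic
taof(Hif1a)	increases	r(Slc2a1)	causal	human	coronary artery endothelium	8756616	source:hypoxic
taof(Hif1a)	increases	r(Ldha)	causal	human	lung microvascular endothelium	9113979	source:hypoxic
taof(Hif1a)	increases	r(Epo)	causal	human	kidney	1448077	source:hypoxic
r(Nfe2l2)	increases	p(Nfe2l2)	non-causal	unspecified			
p(Nfe2l2)	increases	taof(Nfe2l2)	non-causal	unspecified			
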