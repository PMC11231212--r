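id	node_type	label
Lumacaftor	Compound	Lumacaftor
CFTR	Gene	CFTR
CFTR_potentiator	Compound	CFTR potentiator
Cystic_fibrosis	Disease	Cystic fibrosis
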