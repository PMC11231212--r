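Lumacaftor	binds	CFTR
CFTR_potentiator	activates	CFTR
CFTR_potentiator	in_trial_for	Cystic_fibrosis
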