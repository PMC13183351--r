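verb_lemma	relation	case	role
videt	nsubj	NOM	A
videt	obj	ACC	P
pomogat	nsubj	NOM	A
pomogat	obl	DAT	P
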