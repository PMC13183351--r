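# sent_id = ru1
1	koska	koska	NOUN	_	Case=Nom|Number=Sing	2	nsubj	_	_
2	vidit	videt	VERB	_	_	0	root	_	_
3	sobaku	sobaka	NOUN	_	Case=Acc|Number=Sing	2	obj	_	_

# sent_id = ru2
1	mama	mama	NOUN	_	Case=Nom|Number=Sing	2	nsubj	_	_
2	pomogaet	pomogat	VERB	_	_	0	root	_	_
3	dočke	dočka	NOUN	_	Case=Dat|Number=Sing	2	obl	_	_
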