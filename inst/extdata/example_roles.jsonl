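{"id":"ex1","register":"CDS","language":"english","tokens":["why","did","he","bite","the","horse",",","Anne","?"],"instances":[{"role":"A","span":[2,3],"verb_lemma":"bite","verb_index":3},{"role":"P","span":[4,6],"verb_lemma":"bite","verb_index":3}]}
{"id":"ex2","register":"CDS","language":"english","tokens":["they","were","cooking"],"instances":[{"role":"A","span":[0,1],"verb_lemma":"cook","verb_index":2}]}
{"id":"ex3","register":"ADS","language":"english","tokens":["just","write","it","down"],"instances":[{"role":"P","span":[2,3],"verb_lemma":"write","verb_index":1}]}
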