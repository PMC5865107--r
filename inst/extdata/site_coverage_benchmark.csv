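site,n_entomophilous,n_detected
CAD,33,13
LLC,39,17
TRE,31,13
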