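{"ham_f_lp_l":1.2,"glu_f_lp_l":0.9}
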