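name	actual	predicted
all_alpha	CHHHHCHHHHCHHHHCHHHHCHHHH	HHCHHHHCHHHHCHHHHCHHHHCHH
alpha_beta_mixed	CHHHHCEEEECHHHHCEEEECHHHH	HHCHHHHCEEEECHHHHCEEEECHH
alpha_beta_segregated	CHHHHCHHHHCHHHHCEEEECEEEE	EECHHHHCHHHHCHHHHCEEEECEE
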