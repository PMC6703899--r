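mouse_id,sex,group,n_cells
LR00062218,Male,Narcoleptic,27
LR01062918,Female,Narcoleptic,35
LR02082418,Male,Narcoleptic,44
LR03091618,Male,Narcoleptic,42
LR08012219,Female,Narcoleptic,38
LR04101618,Male,Control,38
LR12011419,Male,Control,28
LR13022419,Female,Control,63
LR14022819,Female,Control,35
LR16031319,Male,Control,43
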