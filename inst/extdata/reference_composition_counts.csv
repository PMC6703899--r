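row,total,unscored,AW_ON,REMS_or_REMS_AW_ON,NREMS_or_SC_ON,cross
HAW_ON,112,50,40,13,8,63
EC_ON,74,40,17,17,0,63
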