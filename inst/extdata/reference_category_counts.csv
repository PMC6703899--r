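group,category,count,total,printed_percent
control,REMS_ON,51,207,24.64
control,AW_ON,61,207,29.47
control,REMS_AW_ON,10,207,4.83
control,NREMS_ON,7,207,3.38
control,unscored,98,207,47.34
control,AWO_ON_post_odor,66,207,31.88
narcoleptic,REMS_ON,44,186,23.66
narcoleptic,AW_ON,58,186,31.18
narcoleptic,REMS_AW_ON,13,186,6.99
narcoleptic,NREMS_ON,7,186,3.76
narcoleptic,SC_ON,15,186,8.06
narcoleptic,EC_ON,74,186,39.78
narcoleptic,unscored,79,186,42.47
narcoleptic,HAW_ON_post_odor,112,186,60.22
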