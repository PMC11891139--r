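life_stage,start_md,end_md
embryo,05-15,06-24
yolk_sac_larvae,05-24,07-07
feeding_larvae18,06-20,07-31
feeding_larvae20,06-20,07-31
juvenile,05-01,10-31
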