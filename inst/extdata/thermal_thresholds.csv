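life_stage,optimal_low,optimal_high,critical_low
embryo,14,18,
yolk_sac_larvae,14,20,
feeding_larvae18,14,18,
feeding_larvae20,14,20,
juvenile,14,18,
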