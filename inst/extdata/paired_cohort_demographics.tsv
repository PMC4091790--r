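group	n	mean_age	se_age
young	17	37.7	2.12
aged	17	50.3	2.1
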