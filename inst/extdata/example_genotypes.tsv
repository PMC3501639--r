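sample_id	L1_a	L1_b	L2_a	L2_b	L3_a	L3_b	L4_a	L4_b
ind01	142	146	201	203	95	95	310	314
ind02	142	142	201	205	95	97	310	310
ind03	144	146	203	203	97	97	312	314
ind04	142	146	201	203	95	95	310	314
ind05	144	144	205	205	95	97	312	312
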