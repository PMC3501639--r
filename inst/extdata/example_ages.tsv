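sample_id	age_years
PRI_01	520
PRI_02	640
PRI_03	700
PRI_04	780
PRI_05	650
PRI_06	600
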