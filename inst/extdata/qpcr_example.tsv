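sample_id	conc_41	conc_129	conc_305
FF_intact	10.0	9.8	9.5
FFPE_HQ	10.0	6.0	2.0
FFPE_LQ	8.0	1.6	0.0
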