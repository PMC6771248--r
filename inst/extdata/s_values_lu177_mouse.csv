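organ,s_gy_per_bq_s,ref_mass_g
Heart,4.66e-11,0.141
Lungs,3.78e-11,0.208
Liver,1.47e-11,1.333
Kidneys,3.95e-11,0.362
Spleen,1.62e-10,0.118
Brain,5.21e-11,0.388
Tumors,1.32e-09,0.016
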