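organ,tracer,dose_gy_per_MBq,sd_gy_per_MBq
Heart,Tz-1,1.87e-03,8.74e-04
Heart,Tz-2,2.19e-03,7.61e-04
Heart,Tz-3,1.00e-03,3.29e-04
Heart,Tz-4,3.41e-03,5.38e-04
Lungs,Tz-1,4.37e-03,9.67e-04
Lungs,Tz-2,3.87e-03,1.19e-03
Lungs,Tz-3,2.31e-03,2.75e-03
Lungs,Tz-4,6.41e-03,1.32e-03
Liver,Tz-1,7.56e-02,1.89e-02
Liver,Tz-2,1.60e-02,4.76e-03
Liver,Tz-3,1.05e-03,3.50e-04
Liver,Tz-4,2.06e-02,1.36e-03
Kidneys,Tz-1,2.59e-02,2.52e-03
Kidneys,Tz-2,2.59e-02,2.55e-03
Kidneys,Tz-3,6.62e-03,3.29e-03
Kidneys,Tz-4,2.70e-02,8.25e-04
Spleen,Tz-1,2.30e-02,7.34e-03
Spleen,Tz-2,2.06e-01,2.06e-02
Spleen,Tz-3,2.14e-02,1.56e-02
Spleen,Tz-4,2.56e-02,9.75e-03
Brain,Tz-1,1.16e-03,9.12e-04
Brain,Tz-2,7.95e-04,3.38e-04
Brain,Tz-3,8.63e-04,1.10e-03
Brain,Tz-4,1.13e-03,4.30e-04
Tumors,Tz-1,2.53e-01,1.56e-01
Tumors,Tz-2,5.92e-01,5.22e-01
Tumors,Tz-3,1.83e-01,1.13e-01
Tumors,Tz-4,6.31e-01,5.59e-01
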