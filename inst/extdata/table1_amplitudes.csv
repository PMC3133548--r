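condition,channel,chromophore,mean_umol_l,se_umol_l,snr
MI-simple,1,o2hb,0.101,0.013,0.99
MI-simple,2,o2hb,0.054,0.014,0.54
MI-simple,3,o2hb,0.038,0.011,1.08
MI-simple,overall,o2hb,0.064,0.012,0.87
MI-simple,1,hhb,-0.017,0.002,NA
MI-simple,2,hhb,-0.013,0.003,NA
MI-simple,3,hhb,-0.011,0.003,NA
MI-simple,overall,hhb,-0.014,0.003,NA
MI-complex,1,o2hb,0.192,0.012,1.04
MI-complex,2,o2hb,0.095,0.012,1.23
MI-complex,3,o2hb,0.065,0.010,1.55
MI-complex,overall,o2hb,0.118,0.011,1.27
MI-complex,1,hhb,-0.008,0.006,NA
MI-complex,2,hhb,-0.010,0.003,NA
MI-complex,3,hhb,-0.007,0.003,NA
MI-complex,overall,hhb,-0.009,0.003,NA
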