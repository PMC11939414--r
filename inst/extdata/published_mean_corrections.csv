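algorithm,threshold,total_ml,original_ml,gm_added_ml,csf_removed_ml,enh_removed_ml
HippMapp3r,NA,0.446,4.026,0.337,0.007,0.103
e2dhipseg,0.5,0.509,3.960,0.353,0.009,0.147
hippodeep,0.3,0.564,4.646,0.266,0.025,0.274
AssemblyNet,NA,0.834,4.553,0.336,0.110,0.387
FastSurfer,NA,0.939,5.521,0.201,0.160,0.578
QuickNat,NA,1.141,5.274,0.299,0.263,0.579
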