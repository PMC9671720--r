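sample_id,target_mM,weight_mg,rc_mM,n_possible_rg,highest_rg
1,5,1.03,5.29,17,161
2,30,5.73,29.44,12,90.5
3,50,9.38,48.19,12,90.5
4,80,15.14,77.78,5,40.3
5,110,21.09,108.35,4,36
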