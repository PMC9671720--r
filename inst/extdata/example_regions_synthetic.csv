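label,ppm_high,ppm_low,n_protons
H2,8.85,8.45,1
H8,8.05,7.75,1
H5,7.55,7.28,1
H3,7.28,7.05,1
H7,6.95,6.70,1
OH,5.90,5.60,1
H11,5.45,5.20,1
H9,5.20,4.80,2
OCH3,4.15,3.70,3
H10,3.45,3.15,1
H6a,2.75,2.45,1
H12,2.35,2.10,1
H13,1.90,1.60,2
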