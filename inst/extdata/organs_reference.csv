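organ,volume_L,flow_L_per_h,water,lipid,protein
venous_blood,3.70,NA,0.80,0.01,0.18
arterial_blood,1.85,NA,0.80,0.01,0.18
lung,0.55,390.000,0.80,0.03,0.15
adipose,15.00,19.500,0.15,0.80,0.03
bone,10.50,19.500,0.35,0.10,0.20
brain,1.45,46.800,0.77,0.11,0.08
gut,1.65,58.500,0.75,0.06,0.15
heart,0.33,15.600,0.75,0.10,0.14
kidney,0.31,74.100,0.78,0.05,0.15
liver,1.80,25.350,0.75,0.06,0.16
muscle,28.00,66.300,0.76,0.03,0.17
skin,3.30,19.500,0.70,0.10,0.18
spleen,0.15,11.700,0.78,0.03,0.18
pancreas,0.14,3.900,0.73,0.12,0.13
gonads,0.035,0.195,0.78,0.05,0.15
rest,1.00,29.055,0.70,0.10,0.15
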