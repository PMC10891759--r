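age_years,weight_kg,height_cm,hematocrit
0.25,6.4,61,0.35
0.5,7.6,67,0.36
1,9.5,75,0.36
2,12.3,87,0.37
3,14.2,95,0.37
4,16.3,102,0.375
5,18.4,109,0.38
6,20.7,115,0.38
8,25.8,128,0.39
10,32.0,138,0.395
12,40.0,149,0.40
14,49.0,160,0.41
16,58.0,168,0.42
18,65.0,170,0.44
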