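band,age_lo,age_hi,organ,fraction
infant,0,0.5,venous_blood,0.048
infant,0,0.5,arterial_blood,0.024
infant,0,0.5,lung,0.009
infant,0,0.5,adipose,0.25
infant,0,0.5,bone,0.12
infant,0,0.5,brain,0.09
infant,0,0.5,gut,0.027
infant,0,0.5,heart,0.006
infant,0,0.5,kidney,0.007
infant,0,0.5,liver,0.04
infant,0,0.5,muscle,0.22
infant,0,0.5,skin,0.06
infant,0,0.5,spleen,0.003
infant,0,0.5,pancreas,0.002
infant,0,0.5,gonads,0.0003
infant,0,0.5,rest,0.02
late_infant,0.5,2,venous_blood,0.048
late_infant,0.5,2,arterial_blood,0.024
late_infant,0.5,2,lung,0.009
late_infant,0.5,2,adipose,0.24
late_infant,0.5,2,bone,0.13
late_infant,0.5,2,brain,0.08
late_infant,0.5,2,gut,0.026
late_infant,0.5,2,heart,0.0055
late_infant,0.5,2,kidney,0.0065
late_infant,0.5,2,liver,0.038
late_infant,0.5,2,muscle,0.25
late_infant,0.5,2,skin,0.055
late_infant,0.5,2,spleen,0.0028
late_infant,0.5,2,pancreas,0.002
late_infant,0.5,2,gonads,0.0003
late_infant,0.5,2,rest,0.018
young_child,2,6,venous_blood,0.050
young_child,2,6,arterial_blood,0.025
young_child,2,6,lung,0.0085
young_child,2,6,adipose,0.20
young_child,2,6,bone,0.14
young_child,2,6,brain,0.055
young_child,2,6,gut,0.025
young_child,2,6,heart,0.005
young_child,2,6,kidney,0.006
young_child,2,6,liver,0.034
young_child,2,6,muscle,0.30
young_child,2,6,skin,0.05
young_child,2,6,spleen,0.0026
young_child,2,6,pancreas,0.002
young_child,2,6,gonads,0.0004
young_child,2,6,rest,0.016
child,6,12,venous_blood,0.051
child,6,12,arterial_blood,0.0255
child,6,12,lung,0.008
child,6,12,adipose,0.19
child,6,12,bone,0.145
child,6,12,brain,0.035
child,6,12,gut,0.024
child,6,12,heart,0.005
child,6,12,kidney,0.0055
child,6,12,liver,0.030
child,6,12,muscle,0.34
child,6,12,skin,0.048
child,6,12,spleen,0.0024
child,6,12,pancreas,0.002
child,6,12,gonads,0.0004
child,6,12,rest,0.015
adolescent,12,18,venous_blood,0.052
adolescent,12,18,arterial_blood,0.026
adolescent,12,18,lung,0.008
adolescent,12,18,adipose,0.20
adolescent,12,18,bone,0.148
adolescent,12,18,brain,0.025
adolescent,12,18,gut,0.0235
adolescent,12,18,heart,0.0048
adolescent,12,18,kidney,0.005
adolescent,12,18,liver,0.028
adolescent,12,18,muscle,0.38
adolescent,12,18,skin,0.047
adolescent,12,18,spleen,0.0022
adolescent,12,18,pancreas,0.002
adolescent,12,18,gonads,0.0005
adolescent,12,18,rest,0.0145
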