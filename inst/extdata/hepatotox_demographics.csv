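dimension,level,count,pct_printed
gender,Female,1949,46.46
gender,Male,1121,26.72
gender,Missing,1125,26.82
age,<18,237,5.65
age,>85,21,0.50
age,18-64.9,1512,36.04
age,65-85,709,16.90
age,Missing,1716,40.91
weight,<50 kg,97,2.31
weight,>100 kg,64,1.53
weight,50-100 kg,558,13.30
weight,Missing,3476,82.86
region,US,766,18.26
region,CA,568,13.54
region,IT,348,8.30
region,ES,316,7.53
region,DE,252,6.01
outcome,Death,439,10.46
outcome,Disability,21,0.50
outcome,Hospitalization,725,17.28
outcome,Life-Threatening,188,4.48
outcome,Other and Unknown,2822,67.27
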