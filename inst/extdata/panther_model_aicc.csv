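terms,K,AICc
Estimator,10,786.06
Estimator + Percent fix success + GPS schedule + Number of locations + Study Area,22,807.98
Intercept,3,1098.29
GPS schedule,5,1103.15
Percent fix success,5,1104.77
Number of locations,6,1105.93
Percent fix success + GPS schedule,7,1107.46
GPS schedule + Number of locations,8,1111.06
Study Area,8,1111.12
Percent fix success + GPS schedule + Number of locations,10,1115.40
Number of locations + Study Area,11,1118.28
Number of locations + GPS schedule + Study Area,13,1122.14
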