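patient,p_systolic,p_diastolic,delta_p
1,161.5,73,88.5
2,158.3,77,81.3
3,112.9,73,39.9
4,148.5,80,68.5
5,151.9,105,46.9
6,159.5,75,84.5
7,105.4,75,30.4
8,116.9,74,42.9
9,135,62,73
10,124.4,93,31.4
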