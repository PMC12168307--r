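age_lo,age_hi,n_subjects,upper_cm3,mean_cm3,lower_cm3
6,11.99,121,69.08,55.44,41.8
12,17.99,111,81.26,62.8,44.34
18,23.99,56,89.63,68.35,47.07
24,29.99,87,94.57,74.49,54.41
30,35.99,8,100.91,82.47,64.03
36,41.99,135,113.38,89.6,65.82
42,47.99,77,113.89,94.89,75.89
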