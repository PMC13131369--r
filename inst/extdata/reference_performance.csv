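task,farm,tp_pct,fn_pct,fp_pct,recall,precision,f1
identification,H1,69.01,30.94,6.57,69.05,91.31,78.61
identification,H2,78.05,21.95,12.76,78.05,85.95,81.77
identification,H3,75.36,24.64,15.22,75.36,83.22,79.03
activity,H1,84.78,15.10,6.57,84.88,92.80,88.66
activity,H2,87.86,12.13,12.76,87.86,87.33,87.48
activity,H3,99.01,0.99,15.22,99.01,86.68,92.39
location,H1,84.78,15.10,6.57,84.88,92.80,88.66
location,H2,92.79,7.21,12.76,92.79,87.91,90.31
location,H3,99.01,0.99,15.22,99.01,86.68,92.39
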