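name,measured_MPa,sd_MPa,n
M1,2.93,0.02,5
M1a,1.95,0.04,5
M1b,2.65,0.02,5
M1c,1.44,0.01,5
M2,4.88,0.02,5
M2a,4.98,0.02,5
M2b,4.83,0.01,5
KCl,6.37,0.01,5
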