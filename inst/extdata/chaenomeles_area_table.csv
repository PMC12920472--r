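scenario,period,low,moderate,high
current,current,91.32,148.89,88.20
ssp245,2050s,139.45,131.56,77.25
ssp245,2070s,134.87,140.59,66.59
ssp585,2050s,128.40,139.36,75.38
ssp585,2070s,152.14,131.18,64.11
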