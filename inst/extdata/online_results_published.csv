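subject,averaging_times,pattern,accuracy_pct,itr_bits_min
S1,4,black,99.01,38.08
S2,4,black,96.25,34.20
S3,6,black,90.18,23.68
S4,6,black,89.38,23.03
S5,6,black,86.25,20.65
S6,6,black,80.00,16.46
S7,6,black,65.63,9.03
S8,6,black,62.50,7.73
S9,6,black,44.37,2.19
S1,4,white,99.69,39.30
S2,4,white,98.75,37.66
S3,6,white,97.50,30.72
S4,6,white,88.12,22.04
S5,6,white,96.88,30.00
S6,6,white,81.25,17.26
S7,6,white,61.16,7.21
S8,6,white,81.87,17.65
S9,6,white,77.08,14.74
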