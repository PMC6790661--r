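option,rank,probability,cumulative
D,1,0.54,0.54
D,2,0.33,0.86
D,3,0.09,0.96
D,4,0.03,0.99
D,5,0.01,1.00
D,6,0.00,1.00
D,7,0.00,1.00
F,1,0.33,0.33
F,2,0.25,0.58
F,3,0.06,0.63
F,4,0.09,0.72
F,5,0.09,0.81
F,6,0.10,0.92
F,7,0.08,1.00
C,1,0.04,0.04
C,2,0.21,0.25
C,3,0.38,0.63
C,4,0.23,0.86
C,5,0.12,0.98
C,6,0.03,1.00
C,7,0.00,1.00
A,1,0.01,0.01
A,2,0.11,0.12
A,3,0.31,0.43
A,4,0.39,0.81
A,5,0.16,0.97
A,6,0.03,1.00
A,7,0.00,1.00
G,1,0.01,0.01
G,2,0.07,0.08
G,3,0.11,0.19
G,4,0.15,0.35
G,5,0.20,0.55
G,6,0.16,0.71
G,7,0.29,1.00
B,1,0.07,0.07
B,2,0.04,0.11
B,3,0.03,0.15
B,4,0.05,0.19
B,5,0.13,0.33
B,6,0.27,0.60
B,7,0.41,1.00
E,1,0.00,0.00
E,2,0.00,0.01
E,3,0.01,0.02
E,4,0.07,0.09
E,5,0.28,0.36
E,6,0.42,0.78
E,7,0.22,1.00
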