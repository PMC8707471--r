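"R","spo2"
0.4,100
0.5,97.5
0.6,95
0.7,92.5
0.8,90
0.9,87.5
1,85
1.1,82.5
1.2,80
1.3,77.5
1.4,75
1.5,72.5
1.6,70
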