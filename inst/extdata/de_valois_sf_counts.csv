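bin_edge_low_cpd,bin_edge_high_cpd,count
0.35,0.5,0
0.5,0.7,3
0.7,1.0,3
1.0,1.4,6
1.4,2.0,17
2.0,2.8,22
2.8,4.0,18
4.0,5.6,19
5.6,8.0,9
8.0,11.2,4
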