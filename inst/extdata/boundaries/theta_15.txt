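# Theta cut-points (degrees), 15 bins; fitted on the packaged synthetic sample
0.5930
3.0485
5.4915
8.8515
12.0955
15.9675
20.7135
26.1155
30.7255
37.5965
46.2825
56.6955
66.1965
77.8915
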