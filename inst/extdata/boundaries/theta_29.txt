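# Theta cut-points (degrees), 29 bins; fitted on the packaged synthetic sample
0.0420
0.7580
2.1795
3.2695
4.5705
5.9065
7.6005
9.4635
11.1875
12.7395
14.9635
17.0315
19.2845
22.1315
24.8205
27.4425
29.7485
32.2855
35.8255
40.3265
45.1915
49.9745
55.4985
60.5795
65.3965
71.1285
77.3335
83.9485
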