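# Theta cut-points (degrees), 21 bins; fitted on the packaged synthetic sample
0.0420
1.8200
3.4515
5.3550
7.4445
9.9775
12.0955
15.0655
17.9365
21.4625
25.3875
28.7555
32.0385
37.5965
43.5145
50.4855
58.1055
64.6305
72.4325
81.3785
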