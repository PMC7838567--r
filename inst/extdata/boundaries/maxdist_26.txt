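# MaxDist cut-points (Angstrom), 26 bins; fitted on the packaged synthetic sample
9.0425
10.8355
12.8985
14.3190
15.8465
16.9445
18.4375
19.9725
21.0595
22.6160
24.0680
25.7415
26.9995
28.7155
30.3365
31.9655
34.1045
36.3395
39.1140
42.1105
46.1220
52.4485
59.4460
70.9630
80.8610
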