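# MaxDist cut-points (Angstrom), 35 bins; fitted on the packaged synthetic sample
8.5920
10.0770
11.5135
12.8035
14.2610
15.2880
16.2775
16.7815
18.4115
19.2340
19.9735
21.0560
22.1975
23.1000
24.4220
25.4525
26.3935
27.0185
28.7180
30.1210
31.5805
33.0005
34.7175
36.2285
37.5305
39.6085
42.1105
45.1650
49.5095
52.8480
59.4460
67.6630
77.5615
87.4600
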