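# MaxDist cut-points (Angstrom), 12 bins; fitted on the packaged synthetic sample
11.3550
15.0495
18.0025
20.7605
23.6335
26.9995
30.3410
34.7705
40.1630
49.5095
67.6630
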