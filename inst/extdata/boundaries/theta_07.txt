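# Theta cut-points (degrees), 7 bins; fitted on the packaged synthetic sample
3.4515
9.9775
17.9365
28.7555
43.5145
64.6305
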