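NRRD0004
type: double
dimension: 3
sizes: 3 3 2
spacings: 6.1 6.1 8
axis mins: 0 0 0
encoding: ascii
endian: little
probeloc_axis_order:=ML DV AP
probeloc_space:=subject

1 2 3 4 5 6 7 8 9 10 11 12 13 14 15 16 17 18
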