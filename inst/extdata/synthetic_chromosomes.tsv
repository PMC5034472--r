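probe	chromosome
P1	chr1
P2	chr1
P3	chr2
P4	chr2
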