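quantity,cardiac_index,cardiac_output
bias,0.02,0.04
precision,0.20,0.34
loa_upper,0.41,0.71
loa_lower,-0.37,-0.64
mpe,14.7,14.6
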