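E01 1 0
E02 0.7071 0.7071
E03 0 1
E04 -0.7071 0.7071
E05 -1 0
E06 -0.7071 -0.7071
E07 0 -1
E08 0.7071 -0.7071
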