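sex	group_I	group_II
f	9	13
m	10	7
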