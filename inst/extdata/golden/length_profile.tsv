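length	count	frequency
85	59	0.98333333
86	1	0.01666667
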