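node	value
A	3.3219280948873622
B	2.3421440421990942
C	1.7843428381831106
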