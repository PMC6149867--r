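pair	count
C/T	38758
A/G	39805
A/T	11838
A/C	10256
T/G	10298
C/G	8456
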