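sample	sex
EUCO_F1	F
EUCO_F2	F
EUCO_F3	F
EUCO_M1	M
EUCO_M2	M
EUCO_M3	M
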