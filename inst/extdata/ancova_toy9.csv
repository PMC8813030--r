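subject,group,age,y
s1,A,20,10
s2,A,30,13
s3,A,40,14
s4,B,22,15
s5,B,32,18
s6,B,42,18
s7,C,24,21
s8,C,34,22
s9,C,44,25
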