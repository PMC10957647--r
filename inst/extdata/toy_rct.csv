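id,time,status,exposure
1,1,1,1
2,3,1,1
3,2,1,0
4,4,0,0
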