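baseline_type,future_type,departure
1,1,0
1,2,1
1,3,2
1,4,3
1,5,3
2,1,1
2,2,0
2,3,1
2,4,2
2,5,3
3,1,2
3,2,1
3,3,0
3,4,1
3,5,2
4,1,3
4,2,2
4,3,1
4,4,0
4,5,1
5,1,3
5,2,3
5,3,2
5,4,1
5,5,0
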