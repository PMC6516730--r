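train_id,interval_index,attended_component
1,1,1
1,2,2
1,3,2
1,4,1
1,5,1
1,6,1
1,7,1
1,8,1
1,9,1
1,10,1
1,11,1
1,12,1
1,13,2
1,14,2
1,15,2
2,1,1
2,2,1
2,3,1
2,4,1
2,5,1
2,6,1
2,7,1
2,8,1
2,9,1
2,10,1
2,11,1
2,12,1
2,13,1
2,14,1
2,15,1
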