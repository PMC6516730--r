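train_id,spike_time_s
1,1.004000
1,1.061500
1,1.081900
1,1.174400
1,1.194600
1,1.217300
1,1.399100
1,1.420800
1,1.455200
1,1.470200
2,1.003300
2,1.043400
2,1.081900
2,1.153000
2,1.212700
2,1.224600
2,1.238900
2,1.256700
2,1.276300
2,1.301700
2,1.451100
2,1.480600
2,1.497900
# window,1.000000,1.500000
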