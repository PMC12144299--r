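1000001,10,5,9,8,10,4,3,7,5,2
1000002,3,4,2,6,1,2,4,2,2,4
1000003,7,6,5,10,8,2,10,5,6,2
1000004,2,10,8,8,9,8,1,1,8,2
1000005,10,?,10,7,9,5,6,6,4,4
1000006,6,2,8,9,6,1,10,8,9,4
1000007,8,4,10,9,4,5,10,2,9,2
1000008,8,6,10,8,8,9,10,7,7,2
1000009,3,8,8,6,4,6,9,6,4,2
1000010,8,8,2,6,6,8,8,4,9,4
1000011,8,1,7,4,8,10,1,9,8,4
1000012,6,?,5,1,8,2,10,3,3,2
1000013,8,9,6,7,9,4,2,2,8,2
1000014,10,3,3,7,2,1,3,8,6,2
1000015,3,5,5,2,3,6,8,5,5,2
1000016,4,8,9,1,2,4,5,3,9,4
1000017,8,9,7,1,2,10,2,2,10,4
1000018,2,5,8,1,5,7,7,9,5,4
1000019,6,6,2,2,7,7,2,9,3,2
1000020,6,8,2,9,2,10,1,8,3,4
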