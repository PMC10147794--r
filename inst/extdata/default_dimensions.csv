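level,width,depth,height,ivd_height
T1,26,16,13,4
T2,27,16.9375,13.625,4.25
T3,28,17.875,14.25,4.5
T4,29,18.8125,14.875,4.75
T5,30,19.75,15.5,5
T6,31,20.6875,16.125,5.25
T7,32,21.625,16.75,5.5
T8,33,22.5625,17.375,5.75
T9,34,23.5,18,6
T10,35,24.4375,18.625,6.25
T11,36,25.375,19.25,6.5
T12,37,26.3125,19.875,6.75
L1,38,27.25,20.5,7
L2,39,28.1875,21.125,7.25
L3,40,29.125,21.75,7.5
L4,41,30.0625,22.375,7.75
L5,42,31,23,0
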