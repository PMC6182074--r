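feature_id,rc
P1,-0.0117
P2,-0.0417
P3,0.0001
P4,0.0722
P5,0.0071
P6,-0.1063
P7,-0.1002
P8,-0.0453
P9,-0.02
P10,-0.0445
P11,-0.0627
P12,-0.0358
P13,0.0183
P14,0.0047
P15,0.0205
P16,0.0184
P17,0.0348
P18,0.0066
P19,0.005
P20,-0.0046
P21,-0.0263
P22,-0.0186
P23,-0.0097
P24,0.0276
P25,-0.0003
P26,-0.0119
P27,0.0069
P28,-0.0128
P29,0.0016
P30,0.0149
P31,0.0823
N1,-0.0655
N2,0.0559
N3,0.0469
N4,-0.0379
N5,0.0724
N6,0.0036
N7,0.0763
N8,0.0842
N9,0.0513
N10,-0.026
N11,-0.0415
N12,0.0828
N13,0.0491
N14,-0.0203
N15,-0.0309
N16,0.0947
N17,-0.0623
N18,-0.0331
N19,-0.0807
N20,-0.0957
N21,-0.0066
N22,0.0726
N23,0.0131
N24,-0.0403
N25,-0.0759
N26,-0.0036
N27,0.0685
N28,-0.0059
N29,0.0273
N30,0.0742
N31,0.0765
N32,-0.0016
N33,-0.0114
N34,-0.0237
N35,0.0212
N36,-0.0144
N37,-0.0658
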