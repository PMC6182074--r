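run,SOP,SCU,PHE,RHE,DIC,KOC
V1,47,17,12,4,1,19
V2,34,12,8,18,4,25
V3,27,6,1,53,3,11
V4,22,1,31,5,12,29
V5,18,33,9,13,10,17
V6,14,19,3,41,10,12
V7,12,10,39,3,20,17
V8,9,3,20,18,31,19
V9,7,51,3,21,13,5
V10,5,25,46,1,19,5
V11,3,14,23,13,42,6
V12,1,6,10,38,43,2
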