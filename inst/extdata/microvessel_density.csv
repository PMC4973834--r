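study_id,method,y,se
1,chalkley,0.122,0.087
3,chalkley,0.039,0.06
4,all_vessels,-0.02,0.09
5,all_vessels,0.058,0.063
6,chalkley,0.104,0.065
6,all_vessels,0.02,0.091
7,chalkley,0.039,0.038
8,all_vessels,0.239,0.039
9,all_vessels,-0.211,0.221
10,all_vessels,0.03,0.061
11,all_vessels,-0.01,0.02
12,all_vessels,0.307,0.252
13,chalkley,0.02,0.066
13,all_vessels,0,0.025
14,all_vessels,-0.693,0.758
15,all_vessels,-0.174,0.142
16,all_vessels,-0.02,0.025
17,chalkley,0.03,0.047
17,all_vessels,0.049,0.037
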