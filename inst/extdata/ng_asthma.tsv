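# Number of visits to the emergency department during the first three
# months after discharge, by asthma education programme arm
# (standard n = 45, intensive n = 55); scale {0,1,2,3,4}.
value	standard	intensive
0	19	39
1	10	8
2	7	8
3	3	0
4	6	0
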