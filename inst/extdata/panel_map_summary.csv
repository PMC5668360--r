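level,n_markers,n_positions,length_cM
1A,838,308,129
1B,905,250,136
1D,222,112,137
2A,777,226,128
2B,1074,286,147
2D,204,109,159
3A,909,267,156
3B,1175,282,145
3D,246,120,152
4A,652,276,168
4B,490,184,113
4D,237,120,129
5A,922,350,190
5B,1057,340,172
5D,236,147,198
6A,590,208,127
6B,893,237,114
6D,209,101,142
7A,1068,319,164
7B,814,221,147
7D,229,140,171
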