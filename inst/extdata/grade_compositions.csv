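grade,max_grain_size_mm,f_lt5,f_5_15,f_15_50,f_50_80,f_80_120,f_gt120
1,4,1.000,0.000,0.000,0.000,0.000,0.000
2,12,0.589,0.411,0.000,0.000,0.000,0.000
3,22,0.456,0.367,0.177,0.000,0.000,0.000
4,34,0.388,0.346,0.266,0.000,0.000,0.000
5,48,0.353,0.330,0.317,0.000,0.000,0.000
6,64,0.312,0.286,0.263,0.139,0.000,0.000
7,82,0.309,0.242,0.206,0.167,0.076,0.000
8,102,0.283,0.211,0.178,0.156,0.172,0.000
9,122,0.255,0.217,0.167,0.132,0.123,0.106
10,142,0.223,0.203,0.152,0.130,0.145,0.147
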