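level,a,b,c
0,0,0,8.5
1,37.037037,0.5555556,8.5
2,44.8148148,0.6111111,8.5
3,53.3333333,0.6666667,8.5
4,62.5925926,0.7222222,8.5
5,72.5925926,0.7777778,8.5
6,83.3333333,0.8333333,8.5
7,94.8148148,0.8888889,8.5
8,107.037037,0.9444444,8.5
9,120,1,8.5
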