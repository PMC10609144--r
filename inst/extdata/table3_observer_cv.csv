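observer,cv
1,16.9
2,13.4
3,16.3
4,16.0
5,18.1
6,13.4
7,15.8
8,15.5
9,18.3
10,12.3
11,16.0
12,17.6
13,20.3
14,13.7
15,14.8
16,16.2
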