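id,L,x,y,matched_L
1,40.49,0.7077,0.2834,164.42
2,64.6,0.105,0.818,136.27
3,9.803,0.1547,0.0247,83.42
4,47.28,0.3005,0.0891,181.60
5,189.2,0.4098,0.5527,209.76
6,93.27,0.1451,0.1876,169.95
7,32.11,0.1646,0.1179,101.45
8,19.12,0.2178,0.0852,91.22
9,26.22,0.3944,0.1975,87.07
10,46.22,0.4831,0.3827,92.50
11,52.34,0.295,0.5529,96.60
12,46.75,0.1843,0.3489,85.45
13,37.97,0.6481,0.3394,122.83
14,25.35,0.5448,0.2048,154.99
15,48.93,0.1278,0.4824,117.86
16,46.6,0.2216,0.7145,125.47
17,11.17,0.171,0.0285,110.54
18,25.09,0.152,0.0644,121.41
19,94.87,0.3736,0.3599,123.59
20,73.3,0.2002,0.1866,124.05
21,70.26,0.2507,0.1768,125.90
22,90.06,0.2312,0.3247,130.80
23,103.2,0.2929,0.4299,138.02
24,75.37,0.3328,0.2518,129.24
25,73.46,0.1155,0.6494,163.40
26,39.43,0.6429,0.2504,171.36
27,47.28,0.6454,0.2833,164.46
28,87.01,0.1831,0.6596,164.37
29,49.8,0.6668,0.3097,155.87
30,78.57,0.1357,0.7655,156.26
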