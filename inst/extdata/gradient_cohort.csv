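case,B0,B0_se,B1,B1_se,R2,ptv_volume_cc
1,102.835,0.604,-30.853,0.570,0.992,58.5
2,100.209,0.677,-24.880,0.553,0.989,188.7
3,102.212,0.664,-26.104,0.538,0.993,99.8
4,101.796,0.529,-29.971,0.498,0.993,54.4
5,100.640,0.566,-30.156,0.554,0.992,97.8
6,102.823,0.629,-30.054,0.578,0.991,67.0
7,100.037,0.608,-26.939,0.540,0.990,143.6
8,101.647,0.616,-29.672,0.576,0.991,83.6
9,100.954,0.650,-26.042,0.544,0.989,135.9
10,100.935,0.637,-27.477,0.563,0.990,123.8
11,101.848,0.665,-24.424,0.509,0.989,119.6
12,102.802,0.669,-28.647,0.586,0.990,80.1
13,103.242,0.605,-30.604,0.559,0.992,47.4
14,102.487,0.615,-31.006,0.588,0.991,69.8
15,101.958,0.521,-27.877,0.454,0.993,62.3
16,99.856,0.612,-29.021,0.589,0.989,137.2
17,101.298,0.670,-23.860,0.510,0.989,231.7
18,101.651,0.718,-26.193,0.596,0.987,145.5
19,101.608,0.541,-32.499,0.555,0.993,46.4
20,101.909,0.533,-31.098,0.519,0.993,58.7
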