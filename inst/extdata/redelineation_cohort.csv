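case,gtv_pre_cc,gtv_post_cc,v_i_cc,jc,dsc,jc_ev,dsc_ev
1,38.5,42.1,35.5,0.787,0.881,0.933,0.965
2,124.3,130.7,112.3,0.787,0.881,0.928,0.963
3,65.7,71.3,60.2,0.784,0.879,0.924,0.960
4,35.8,37.4,33.0,0.821,0.902,0.945,0.972
5,64.4,58.4,53.3,0.767,0.868,0.919,0.958
6,44.1,48.9,41.8,0.816,0.899,0.944,0.971
7,94.6,86.7,79.9,0.788,0.881,0.920,0.958
8,55.1,60.6,52.1,0.819,0.901,0.943,0.970
9,89.5,85.6,78.2,0.807,0.893,0.932,0.965
10,81.5,90.0,76.3,0.801,0.890,0.929,0.963
11,78.5,82.3,71.5,0.801,0.889,0.935,0.966
12,52.7,48.2,43.0,0.743,0.852,0.913,0.955
13,31.2,33.7,29.4,0.828,0.906,0.947,0.973
14,45.6,55.0,43.2,0.753,0.859,0.918,0.957
15,41.0,39.5,36.4,0.825,0.904,0.944,0.971
16,90.3,95.9,81.6,0.780,0.876,0.924,0.960
17,152.6,132.1,117.5,0.703,0.825,0.883,0.938
18,96.0,110.8,90.2,0.774,0.872,0.913,0.955
19,30.6,32.7,28.5,0.819,0.900,0.946,0.972
20,38.7,40.5,35.9,0.829,0.907,0.949,0.974
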