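"pct_stride","hip_deg","knee_deg","ankle_deg"
0,29.22,5.41,6.7
1,28.79,5.95,6.92
2,28.26,6.6,7.13
3,27.63,7.34,7.32
4,26.92,8.16,7.48
5,26.13,9.05,7.62
6,25.24,9.98,7.74
7,24.28,10.92,7.84
8,23.25,11.86,7.92
9,22.14,12.76,7.97
10,20.96,13.6,7.99
11,19.72,14.38,8
12,18.42,15.07,7.98
13,17.07,15.67,7.94
14,15.67,16.18,7.87
15,14.23,16.61,7.78
16,12.76,16.96,7.67
17,11.25,17.27,7.53
18,9.72,17.54,7.38
19,8.17,17.8,7.2
20,6.6,18.06,7
21,5.03,18.34,6.78
22,3.46,18.67,6.54
23,1.9,19.04,6.29
24,0.35,19.47,6.02
25,-1.19,19.96,5.73
26,-2.69,20.5,5.43
27,-4.17,21.11,5.11
28,-5.61,21.76,4.78
29,-7.01,22.45,4.44
30,-8.37,23.18,4.09
31,-9.67,23.92,3.73
32,-10.91,24.68,3.37
33,-12.09,25.44,2.99
34,-13.2,26.2,2.61
35,-14.24,26.94,2.22
36,-15.21,27.66,1.81
37,-16.09,28.36,1.4
38,-16.89,29.04,0.96
39,-17.61,29.68,0.5
40,-18.23,30.3,0.01
41,-18.77,30.88,-0.53
42,-19.21,31.43,-1.14
43,-19.55,31.96,-1.81
44,-19.8,32.46,-2.58
45,-19.95,32.95,-3.46
46,-20,33.43,-4.45
47,-19.95,33.9,-5.57
48,-19.81,34.38,-6.8
49,-19.56,34.87,-8.15
50,-19.22,35.38,-9.58
51,-18.79,35.93,-11.05
52,-18.26,36.52,-12.51
53,-17.63,37.15,-13.92
54,-16.92,37.83,-15.2
55,-16.13,38.57,-16.29
56,-15.24,39.35,-17.13
57,-14.28,40.18,-17.69
58,-13.25,41.03,-17.92
59,-12.14,41.9,-17.81
60,-10.96,42.76,-17.39
61,-9.72,43.59,-16.67
62,-8.42,44.35,-15.7
63,-7.07,45.03,-14.54
64,-5.67,45.57,-13.25
65,-4.23,45.96,-11.9
66,-2.76,46.17,-10.54
67,-1.25,46.15,-9.22
68,0.28,45.9,-7.98
69,1.83,45.4,-6.85
70,3.4,44.64,-5.83
71,4.97,43.61,-4.92
72,6.54,42.33,-4.13
73,8.1,40.81,-3.44
74,9.65,39.07,-2.83
75,11.19,37.15,-2.29
76,12.69,35.07,-1.81
77,14.17,32.88,-1.36
78,15.61,30.61,-0.95
79,17.01,28.3,-0.55
80,18.37,25.99,-0.16
81,19.67,23.71,0.22
82,20.91,21.5,0.6
83,22.09,19.38,0.98
84,23.2,17.37,1.36
85,24.24,15.49,1.74
86,25.21,13.74,2.12
87,26.09,12.15,2.5
88,26.89,10.7,2.87
89,27.61,9.4,3.24
90,28.23,8.25,3.61
91,28.77,7.23,3.97
92,29.21,6.35,4.32
93,29.55,5.59,4.66
94,29.8,4.95,5
95,29.95,4.42,5.32
96,30,3.99,5.62
97,29.95,3.65,5.92
98,29.81,3.4,6.2
99,29.56,3.24,6.46
100,29.22,3.15,6.7
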