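"n","M"
8,39.013
11,59.188
13,73.304
15,88.341
16,91.142
20,126.413
29,217.106
30,231.308
33,238.495
38,269.17
44,332.045
45,333.932
53,443.342
55,470.868
58,494.956
59,487.302
60,522.41
61,516.126
63,525.979
64,581.309
66,569.337
68,546.333
69,577.721
72,598.779
74,654.93
77,690.497
84,795.579
87,876.827
90,909.58
95,797.223
106,1003.764
118,987.368
123,1236.123
127,1348.879
129,1293.315
130,1355.22
137,1259.275
138,1273.299
139,1294.553
143,1397.979
144,1585.294
146,1417.924
147,1562.742
149,1332.164
153,1380.802
154,1574.874
163,1571.024
167,1784.996
168,1717.578
176,1768.704
178,1818.493
183,2027.462
184,1867.448
187,1970.799
192,1924.501
193,2050.925
194,2035.878
197,1927.536
199,2139.482
200,2197.035
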