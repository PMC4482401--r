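# SWC written by dendrim
1 1 0.000000 0.000000 0.000000 6.000000 -1
2 3 0.796691 1.388479 9.662812 0.510575 1
3 3 0.548555 4.922653 18.794108 0.506693 2
4 3 4.031408 4.814437 27.947825 0.502812 3
5 3 8.918151 1.846332 35.900348 0.498931 4
6 3 8.571976 3.497607 45.548456 0.495050 5
7 3 6.187600 6.748076 51.802567 0.614535 6
8 3 3.604312 8.467056 58.565438 0.581535 7
9 3 1.928176 9.305105 65.766337 0.548535 8
10 3 -1.640771 9.908848 72.267323 0.515535 9
11 3 -5.028929 15.727276 75.434495 0.482535 10
12 3 2.830977 0.761923 37.683217 0.654471 6
13 3 -5.343675 1.553735 31.779564 0.615304 12
14 3 -14.292612 0.683889 27.146540 0.576137 13
15 3 -21.327582 -4.663470 22.225162 0.536970 14
16 3 -27.961186 -7.707700 15.222806 0.497802 15
17 3 -3.927833 19.818356 77.505315 0.695133 11
18 3 -4.199798 22.170941 81.583184 0.678518 17
19 3 -5.897353 25.143165 84.826922 0.661904 18
20 3 -6.877976 27.518281 88.781013 0.645290 19
21 3 -7.721342 30.286792 92.504147 0.628675 20
22 3 -1.603073 12.406611 82.430521 0.496561 11
23 3 -3.315725 13.676684 90.625728 0.478023 22
24 3 -2.824710 13.381021 99.074347 0.459484 23
25 3 -3.750038 14.718635 107.384716 0.440946 24
26 3 -1.617866 14.140804 115.559532 0.422407 25
27 3 -20.886744 27.923081 92.188992 0.433731 21
28 3 -33.333350 27.450282 97.074963 0.432830 27
29 3 -46.528169 28.255573 95.010377 0.431930 28
30 3 -58.710421 30.859207 99.891781 0.431029 29
31 3 -69.978549 33.204840 106.713919 0.430128 30
32 3 -4.643513 27.088108 97.265285 0.740258 21
33 3 0.290159 28.681756 101.201300 0.687451 32
34 3 3.855699 27.449766 106.506218 0.634645 33
35 3 6.350936 31.897136 110.551924 0.581839 34
36 3 8.620788 37.024775 113.857697 0.529033 35
37 3 -77.655308 32.348305 108.597178 0.695852 31
38 3 -83.867644 29.690849 112.787378 0.622109 37
39 3 -91.307076 30.653863 115.421842 0.548366 38
40 3 -97.614935 26.700171 118.213294 0.474622 39
41 3 -104.768681 24.521911 120.913673 0.400879 40
42 3 -75.765556 28.928821 109.903607 0.466226 31
43 3 -78.536528 21.907366 112.132687 0.451855 42
44 3 -80.135225 16.989354 118.066087 0.437485 43
45 3 -80.233391 9.152538 118.788994 0.423114 44
46 3 -82.703039 6.579935 125.805436 0.408744 45
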