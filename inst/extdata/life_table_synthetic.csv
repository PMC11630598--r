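# Synthetic Gompertz background life table: q(age) = min(1, a*exp(b*age))
# with a = 6.08e-5, b = 0.09 (life expectancy ~75 at birth).
# Stand-in for the national life table, which is not redistributed.
age,q
0,6.08e-05
1,6.652579645e-05
2,7.279081568e-05
3,7.96458386e-05
4,8.714642841e-05
5,9.535338088e-05
6,0.0001043332172
7,0.0001141587232
8,0.0001249095392
9,0.0001366728056
10,0.0001495438692
11,0.0001636270559
12,0.0001790365167
13,0.0001958971524
14,0.0002143456264
15,0.0002345314723
16,0.0002566183057
17,0.0002807851508
18,0.0003072278912
19,0.0003361608578
20,0.0003678185658
21,0.0004024576158
22,0.0004403587735
23,0.0004818292456
24,0.0005272051696
25,0.0005768543389
26,0.000631179183
27,0.0006906200305
28,0.0007556586771
29,0.0008268222918
30,0.0009046876889
31,0.0009898860039
32,0.001083107809
33,0.001185108711
34,0.001296715475
35,0.001418832727
36,0.001552450282
37,0.001698651176
38,0.001858620433
39,0.002033654681
40,0.002225172654
41,0.002434726695
42,0.002664015338
43,0.002914897074
44,0.003189405418
45,0.003489765388
46,0.003818411544
47,0.004178007716
48,0.0045714686
49,0.005001983381
50,0.005473041583
51,0.005988461354
52,0.006552420412
53,0.007169489911
54,0.007844671488
55,0.008583437806
56,0.009391776914
57,0.01027624078
58,0.01124399839
59,0.01230289389
60,0.01346151011
61,0.01472923818
62,0.01611635363
63,0.01763409969
64,0.0192947784
65,0.02111185033
66,0.02310004372
67,0.02527547379
68,0.02765577343
69,0.03026023608
70,0.03310997214
71,0.03622808005
72,0.03963983353
73,0.04337288646
74,0.04745749698
75,0.05192677276
76,0.05681693939
77,0.06216763396
78,0.06802222636
79,0.0744281708
80,0.08143739048
81,0.08910669839
82,0.09749825788
83,0.1066800865
84,0.1167266072
85,0.1277192518
86,0.1397471209
87,0.1529077059
88,0.1673076796
89,0.1830637605
90,0.200303659
91,0.2191671126
92,0.2398070184
93,0.2623906726
94,0.2871011263
95,0.3141386692
96,0.3437224533
97,0.3760922692
98,0.4115104892
99,0.4502641948
100,0.4926675028
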