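position	guide_base	target_base	penalty
1	C	A	0.539
2	C	A	0.4575
3	C	A	0.3893
4	C	A	0.3325
5	C	A	0.2849
6	C	A	0.2453
7	C	A	0.2121
8	C	A	0.1844
9	C	A	0.1613
10	C	A	0.142
11	C	A	0.1258
12	C	A	0.1123
13	C	A	0.1011
14	C	A	0.0917
15	C	A	0.0838
16	C	A	0.0773
17	C	A	0.0718
18	C	A	0.0672
19	C	A	0.0634
20	C	A	0.0602
1	G	A	0.98
2	G	A	0.8317
3	G	A	0.7079
4	G	A	0.6045
5	G	A	0.5181
6	G	A	0.4459
7	G	A	0.3856
8	G	A	0.3353
9	G	A	0.2932
10	G	A	0.2581
11	G	A	0.2288
12	G	A	0.2043
13	G	A	0.1838
14	G	A	0.1667
15	G	A	0.1524
16	G	A	0.1405
17	G	A	0.1305
18	G	A	0.1222
19	G	A	0.1152
20	G	A	0.1094
1	T	A	0.539
2	T	A	0.4575
3	T	A	0.3893
4	T	A	0.3325
5	T	A	0.2849
6	T	A	0.2453
7	T	A	0.2121
8	T	A	0.1844
9	T	A	0.1613
10	T	A	0.142
11	T	A	0.1258
12	T	A	0.1123
13	T	A	0.1011
14	T	A	0.0917
15	T	A	0.0838
16	T	A	0.0773
17	T	A	0.0718
18	T	A	0.0672
19	T	A	0.0634
20	T	A	0.0602
1	A	C	0.539
2	A	C	0.4575
3	A	C	0.3893
4	A	C	0.3325
5	A	C	0.2849
6	A	C	0.2453
7	A	C	0.2121
8	A	C	0.1844
9	A	C	0.1613
10	A	C	0.142
11	A	C	0.1258
12	A	C	0.1123
13	A	C	0.1011
14	A	C	0.0917
15	A	C	0.0838
16	A	C	0.0773
17	A	C	0.0718
18	A	C	0.0672
19	A	C	0.0634
20	A	C	0.0602
1	G	C	0.539
2	G	C	0.4575
3	G	C	0.3893
4	G	C	0.3325
5	G	C	0.2849
6	G	C	0.2453
7	G	C	0.2121
8	G	C	0.1844
9	G	C	0.1613
10	G	C	0.142
11	G	C	0.1258
12	G	C	0.1123
13	G	C	0.1011
14	G	C	0.0917
15	G	C	0.0838
16	G	C	0.0773
17	G	C	0.0718
18	G	C	0.0672
19	G	C	0.0634
20	G	C	0.0602
1	T	C	0.98
2	T	C	0.8317
3	T	C	0.7079
4	T	C	0.6045
5	T	C	0.5181
6	T	C	0.4459
7	T	C	0.3856
8	T	C	0.3353
9	T	C	0.2932
10	T	C	0.2581
11	T	C	0.2288
12	T	C	0.2043
13	T	C	0.1838
14	T	C	0.1667
15	T	C	0.1524
16	T	C	0.1405
17	T	C	0.1305
18	T	C	0.1222
19	T	C	0.1152
20	T	C	0.1094
1	A	G	0.98
2	A	G	0.8317
3	A	G	0.7079
4	A	G	0.6045
5	A	G	0.5181
6	A	G	0.4459
7	A	G	0.3856
8	A	G	0.3353
9	A	G	0.2932
10	A	G	0.2581
11	A	G	0.2288
12	A	G	0.2043
13	A	G	0.1838
14	A	G	0.1667
15	A	G	0.1524
16	A	G	0.1405
17	A	G	0.1305
18	A	G	0.1222
19	A	G	0.1152
20	A	G	0.1094
1	C	G	0.539
2	C	G	0.4575
3	C	G	0.3893
4	C	G	0.3325
5	C	G	0.2849
6	C	G	0.2453
7	C	G	0.2121
8	C	G	0.1844
9	C	G	0.1613
10	C	G	0.142
11	C	G	0.1258
12	C	G	0.1123
13	C	G	0.1011
14	C	G	0.0917
15	C	G	0.0838
16	C	G	0.0773
17	C	G	0.0718
18	C	G	0.0672
19	C	G	0.0634
20	C	G	0.0602
1	T	G	0.539
2	T	G	0.4575
3	T	G	0.3893
4	T	G	0.3325
5	T	G	0.2849
6	T	G	0.2453
7	T	G	0.2121
8	T	G	0.1844
9	T	G	0.1613
10	T	G	0.142
11	T	G	0.1258
12	T	G	0.1123
13	T	G	0.1011
14	T	G	0.0917
15	T	G	0.0838
16	T	G	0.0773
17	T	G	0.0718
18	T	G	0.0672
19	T	G	0.0634
20	T	G	0.0602
1	A	T	0.539
2	A	T	0.4575
3	A	T	0.3893
4	A	T	0.3325
5	A	T	0.2849
6	A	T	0.2453
7	A	T	0.2121
8	A	T	0.1844
9	A	T	0.1613
10	A	T	0.142
11	A	T	0.1258
12	A	T	0.1123
13	A	T	0.1011
14	A	T	0.0917
15	A	T	0.0838
16	A	T	0.0773
17	A	T	0.0718
18	A	T	0.0672
19	A	T	0.0634
20	A	T	0.0602
1	C	T	0.98
2	C	T	0.8317
3	C	T	0.7079
4	C	T	0.6045
5	C	T	0.5181
6	C	T	0.4459
7	C	T	0.3856
8	C	T	0.3353
9	C	T	0.2932
10	C	T	0.2581
11	C	T	0.2288
12	C	T	0.2043
13	C	T	0.1838
14	C	T	0.1667
15	C	T	0.1524
16	C	T	0.1405
17	C	T	0.1305
18	C	T	0.1222
19	C	T	0.1152
20	C	T	0.1094
1	G	T	0.539
2	G	T	0.4575
3	G	T	0.3893
4	G	T	0.3325
5	G	T	0.2849
6	G	T	0.2453
7	G	T	0.2121
8	G	T	0.1844
9	G	T	0.1613
10	G	T	0.142
11	G	T	0.1258
12	G	T	0.1123
13	G	T	0.1011
14	G	T	0.0917
15	G	T	0.0838
16	G	T	0.0773
17	G	T	0.0718
18	G	T	0.0672
19	G	T	0.0634
20	G	T	0.0602
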