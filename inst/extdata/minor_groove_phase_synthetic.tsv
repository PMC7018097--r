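offset	phase
-73	minor_out
-72	minor_out
-71	minor_out
-70	unassigned
-69	unassigned
-68	minor_in
-67	minor_in
-66	minor_in
-65	unassigned
-64	unassigned
-63	minor_out
-62	minor_out
-61	minor_out
-60	unassigned
-59	unassigned
-58	minor_in
-57	minor_in
-56	minor_in
-55	unassigned
-54	unassigned
-53	minor_out
-52	minor_out
-51	minor_out
-50	unassigned
-49	unassigned
-48	unassigned
-47	minor_in
-46	minor_in
-45	minor_in
-44	unassigned
-43	unassigned
-42	minor_out
-41	minor_out
-40	minor_out
-39	unassigned
-38	unassigned
-37	minor_in
-36	minor_in
-35	minor_in
-34	unassigned
-33	unassigned
-32	minor_out
-31	minor_out
-30	minor_out
-29	unassigned
-28	unassigned
-27	minor_in
-26	minor_in
-25	minor_in
-24	unassigned
-23	unassigned
-22	minor_out
-21	minor_out
-20	minor_out
-19	unassigned
-18	unassigned
-17	unassigned
-16	minor_in
-15	minor_in
-14	minor_in
-13	unassigned
-12	unassigned
-11	minor_out
-10	minor_out
-9	minor_out
-8	unassigned
-7	unassigned
-6	minor_in
-5	minor_in
-4	minor_in
-3	unassigned
-2	unassigned
-1	minor_out
0	minor_out
1	minor_out
2	unassigned
3	unassigned
4	minor_in
5	minor_in
6	minor_in
7	unassigned
8	unassigned
9	minor_out
10	minor_out
11	minor_out
12	unassigned
13	unassigned
14	minor_in
15	minor_in
16	minor_in
17	unassigned
18	unassigned
19	unassigned
20	minor_out
21	minor_out
22	minor_out
23	unassigned
24	unassigned
25	minor_in
26	minor_in
27	minor_in
28	unassigned
29	unassigned
30	minor_out
31	minor_out
32	minor_out
33	unassigned
34	unassigned
35	minor_in
36	minor_in
37	minor_in
38	unassigned
39	unassigned
40	minor_out
41	minor_out
42	minor_out
43	unassigned
44	unassigned
45	minor_in
46	minor_in
47	minor_in
48	unassigned
49	unassigned
50	unassigned
51	minor_out
52	minor_out
53	minor_out
54	unassigned
55	unassigned
56	minor_in
57	minor_in
58	minor_in
59	unassigned
60	unassigned
61	minor_out
62	minor_out
63	minor_out
64	unassigned
65	unassigned
66	minor_in
67	minor_in
68	minor_in
69	unassigned
70	unassigned
71	minor_out
72	minor_out
73	minor_out
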