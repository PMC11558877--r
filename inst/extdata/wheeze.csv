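ID,Wheeze,City,Age,Smoke
1,1,0,9,0
1,1,0,10,0
1,1,0,11,0
1,0,0,12,0
2,1,1,9,1
2,1,1,10,2
2,0,1,11,2
2,0,1,12,2
3,1,1,9,0
3,0,1,10,0
3,0,1,11,1
3,0,1,12,1
4,0,0,9,0
4,1,0,10,0
4,1,0,11,0
4,0,0,12,1
5,0,1,9,0
5,0,1,10,1
5,0,1,11,1
5,0,1,12,1
6,0,0,9,0
6,0,0,10,1
6,0,0,11,1
6,0,0,12,1
7,0,1,9,1
7,0,1,10,1
7,0,1,11,0
7,0,1,12,0
8,0,0,9,1
8,0,0,10,1
8,0,0,11,1
8,0,0,12,2
9,1,0,9,2
9,0,0,10,2
9,0,0,11,1
9,0,0,12,1
10,0,1,9,0
10,0,1,10,0
10,0,1,11,0
10,0,1,12,1
11,1,1,9,1
11,0,1,10,0
11,1,1,11,0
11,1,1,12,0
12,0,0,9,1
12,0,0,10,0
12,0,0,11,0
12,0,0,12,0
13,0,1,9,1
13,1,1,10,0
13,1,1,11,1
13,1,1,12,1
14,0,0,9,1
14,0,0,10,2
14,0,0,11,1
14,1,0,12,2
15,0,1,9,1
15,0,1,10,1
15,0,1,11,1
15,1,1,12,2
16,1,0,9,1
16,1,0,10,1
16,0,0,11,1
16,0,0,12,1
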