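source,target
4,0
39,0
1,0
34,0
23,0
43,0
14,0
18,0
33,0
21,0
21,1
42,1
46,1
10,1
7,1
9,1
15,1
49,1
37,1
25,1
46,2
37,2
48,2
34,2
42,2
25,2
15,2
33,2
20,2
35,2
6,3
10,3
42,3
38,3
20,3
28,3
45,3
23,3
49,3
40,3
44,4
25,4
6,4
39,4
42,4
47,4
24,4
32,4
14,4
1,4
45,5
18,5
22,5
14,5
38,5
0,5
40,5
6,5
23,5
42,5
40,6
39,6
11,6
17,6
36,6
13,6
49,6
25,6
42,6
23,6
46,7
20,7
39,7
29,7
13,7
22,7
49,7
28,7
33,7
21,7
31,8
38,8
17,8
9,8
39,8
23,8
19,8
26,8
30,8
32,8
39,9
29,9
34,9
10,9
0,9
43,9
26,9
15,9
48,9
24,9
42,10
48,10
12,10
39,10
24,10
28,10
22,10
40,10
33,10
19,10
26,11
35,11
43,11
0,11
29,11
14,11
22,11
5,11
28,11
37,11
46,12
2,12
22,12
35,12
6,12
49,12
41,12
27,12
45,12
20,12
24,13
16,13
19,13
36,13
1,13
0,13
39,13
41,13
12,13
26,13
34,14
1,14
19,14
17,14
49,14
10,14
31,14
35,14
42,14
47,14
45,15
10,15
16,15
40,15
8,15
28,15
24,15
9,15
14,15
37,15
32,16
37,16
39,16
31,16
48,16
29,16
11,16
13,16
38,16
15,16
14,17
1,17
0,17
2,17
8,17
38,17
16,17
20,17
4,17
27,17
44,18
31,18
7,18
36,18
41,18
29,18
21,18
0,18
20,18
24,18
22,19
38,19
15,19
30,19
29,19
1,19
7,19
13,19
36,19
26,19
40,20
37,20
7,20
6,20
36,20
42,20
45,20
8,20
27,20
14,20
38,21
5,21
3,21
35,21
46,21
12,21
41,21
6,21
25,21
31,21
46,22
37,22
28,22
39,22
47,22
19,22
29,22
42,22
40,22
0,22
28,23
13,23
31,23
11,23
29,23
15,23
9,23
34,23
26,23
33,23
3,24
21,24
25,24
23,24
37,24
44,24
14,24
13,24
16,24
17,24
33,25
32,25
7,25
42,25
39,25
6,25
27,25
8,25
19,25
34,25
37,26
29,26
10,26
1,26
2,26
38,26
41,26
14,26
28,26
4,26
28,27
13,27
37,27
43,27
46,27
16,27
0,27
25,27
33,27
18,27
25,28
22,28
3,28
15,28
26,28
39,28
38,28
46,28
34,28
29,28
45,29
35,29
9,29
5,29
39,29
33,29
22,29
44,29
48,29
10,29
12,30
37,30
25,30
47,30
40,30
34,30
3,30
24,30
38,30
16,30
23,31
8,31
45,31
46,31
29,31
48,31
10,31
21,31
32,31
40,31
2,32
18,32
33,32
3,32
12,32
0,32
40,32
4,32
35,32
22,32
28,33
35,33
36,33
8,33
48,33
45,33
19,33
21,33
41,33
42,33
18,34
44,34
17,34
48,34
39,34
28,34
26,34
36,34
31,34
30,34
16,35
37,35
24,35
8,35
20,35
45,35
14,35
48,35
23,35
13,35
6,36
26,36
25,36
29,36
45,36
14,36
5,36
33,36
20,36
0,36
16,37
12,37
45,37
25,37
40,37
1,37
41,37
7,37
24,37
30,37
19,38
46,38
49,38
4,38
9,38
44,38
47,38
14,38
28,38
1,38
0,39
4,39
24,39
36,39
31,39
40,39
12,39
47,39
3,39
37,39
4,40
0,40
37,40
46,40
12,40
7,40
18,40
27,40
47,40
10,40
7,41
22,41
19,41
4,41
1,41
46,41
11,41
2,41
25,41
13,41
12,42
30,42
47,42
33,42
29,42
25,42
6,42
26,42
8,42
7,42
21,43
45,43
5,43
26,43
44,43
29,43
9,43
48,43
0,43
47,43
16,44
12,44
25,44
1,44
31,44
35,44
4,44
22,44
37,44
19,44
27,45
49,45
11,45
34,45
3,45
25,45
12,45
2,45
14,45
33,45
37,46
48,46
3,46
25,46
20,46
44,46
15,46
36,46
23,46
43,46
2,47
25,47
22,47
35,47
21,47
49,47
3,47
45,47
36,47
0,47
46,48
36,48
21,48
20,48
26,48
10,48
43,48
5,48
35,48
41,48
19,49
39,49
32,49
47,49
10,49
44,49
20,49
42,49
16,49
8,49
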