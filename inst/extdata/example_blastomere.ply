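ply
format ascii 1.0
element vertex 42
property float x
property float y
property float z
element face 80
property list uchar int vertex_indices
property int label
end_header
-5.257311121  8.506508084  0.000000000
5.257311121 8.506508084 0.000000000
-5.257311121 -8.506508084  0.000000000
 5.257311121 -8.506508084  0.000000000
 0.000000000 -5.257311121  8.506508084
0.000000000 5.257311121 8.506508084
 0.000000000 -5.257311121 -8.506508084
 0.000000000  5.257311121 -8.506508084
 8.506508084  0.000000000 -5.257311121
8.506508084 0.000000000 5.257311121
-8.506508084  0.000000000 -5.257311121
-8.506508084  0.000000000  5.257311121
-8.090169944  5.000000000  3.090169944
-5.000000000  3.090169944  8.090169944
-3.090169944  8.090169944  5.000000000
3.090169944 8.090169944 5.000000000
 0 10  0
 3.090169944  8.090169944 -5.000000000
-3.090169944  8.090169944 -5.000000000
-5.000000000  3.090169944 -8.090169944
-8.090169944  5.000000000 -3.090169944
-10   0   0
5.000000000 3.090169944 8.090169944
8.090169944 5.000000000 3.090169944
-5.000000000 -3.090169944  8.090169944
 0  0 10
-8.090169944 -5.000000000 -3.090169944
-8.090169944 -5.000000000  3.090169944
  0   0 -10
-5.000000000 -3.090169944 -8.090169944
 8.090169944  5.000000000 -3.090169944
 5.000000000  3.090169944 -8.090169944
 8.090169944 -5.000000000  3.090169944
 5.000000000 -3.090169944  8.090169944
 3.090169944 -8.090169944  5.000000000
-3.090169944 -8.090169944  5.000000000
  0 -10   0
-3.090169944 -8.090169944 -5.000000000
 3.090169944 -8.090169944 -5.000000000
 5.000000000 -3.090169944 -8.090169944
 8.090169944 -5.000000000 -3.090169944
10  0  0
3 0 12 14 1
3 11 13 12 1
3 5 14 13 1
3 12 13 14 1
3 0 14 16 1
3 5 15 14 1
3 1 16 15 1
3 14 15 16 1
3 0 16 18 0
3 1 17 16 0
3 7 18 17 0
3 16 17 18 0
3 0 18 20 0
3 7 19 18 0
3 10 20 19 0
3 18 19 20 0
3 0 20 12 0
3 10 21 20 0
3 11 12 21 1
3 20 21 12 0
3 1 15 23 1
3 5 22 15 1
3 9 23 22 1
3 15 22 23 1
3 5 13 25 1
3 11 24 13 1
3 4 25 24 1
3 13 24 25 1
3 11 21 27 1
3 10 26 21 0
3 2 27 26 0
3 21 26 27 0
3 10 19 29 0
3 7 28 19 0
3 6 29 28 0
3 19 28 29 0
3 7 17 31 0
3 1 30 17 0
3 8 31 30 0
3 17 30 31 0
3 3 32 34 1
3 9 33 32 1
3 4 34 33 1
3 32 33 34 1
3 3 34 36 1
3 4 35 34 1
3 2 36 35 1
3 34 35 36 1
3 3 36 38 0
3 2 37 36 0
3 6 38 37 0
3 36 37 38 0
3 3 38 40 0
3 6 39 38 0
3 8 40 39 0
3 38 39 40 0
3 3 40 32 0
3 8 41 40 0
3 9 32 41 1
3 40 41 32 0
3 4 33 25 1
3 9 22 33 1
3 5 25 22 1
3 33 22 25 1
3 2 35 27 1
3 4 24 35 1
3 11 27 24 1
3 35 24 27 1
3 6 37 29 0
3 2 26 37 0
3 10 29 26 0
3 37 26 29 0
3 8 39 31 0
3 6 28 39 0
3 7 31 28 0
3 39 28 31 0
3 9 41 23 1
3 8 30 41 0
3 1 23 30 0
3 41 30 23 0
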