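P2
24 24
255
0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0
0 0 0 0 0 0 0 2 10 16 20 22 22 20 16 10 2 0 0 0 0 0 0 0
0 0 0 0 0 0 12 22 31 37 42 44 44 42 37 31 22 12 0 0 0 0 0 0
0 0 0 0 4 18 31 42 51 59 64 66 66 64 59 51 42 31 18 4 0 0 0 0
0 0 0 4 20 35 49 61 71 80 85 88 88 85 80 71 61 49 35 20 4 0 0 0
0 0 0 18 35 51 66 80 91 101 107 110 110 107 101 91 80 66 51 35 18 0 0 0
0 0 12 31 49 66 83 97 110 121 129 133 133 129 121 110 97 83 66 49 31 12 0 0
0 2 22 42 61 80 97 114 129 141 150 155 155 150 141 129 114 97 80 61 42 22 2 0
0 10 31 51 71 91 110 129 145 160 171 177 177 171 160 145 129 110 91 71 51 31 10 0
0 16 37 59 80 101 121 141 160 177 190 198 198 190 177 160 141 121 101 80 59 37 16 0
0 20 42 64 85 107 129 150 171 190 208 220 220 208 190 171 150 129 107 85 64 42 20 0
0 22 44 66 88 110 133 155 177 198 220 239 239 220 198 177 155 133 110 88 66 44 22 0
0 22 44 66 88 110 133 155 177 198 220 239 239 220 198 177 155 133 110 88 66 44 22 0
0 20 42 64 85 107 129 150 171 190 208 220 220 208 190 171 150 129 107 85 64 42 20 0
0 16 37 59 80 101 121 141 160 177 190 198 198 190 177 160 141 121 101 80 59 37 16 0
0 10 31 51 71 91 110 129 145 160 171 177 177 171 160 145 129 110 91 71 51 31 10 0
0 2 22 42 61 80 97 114 129 141 150 155 155 150 141 129 114 97 80 61 42 22 2 0
0 0 12 31 49 66 83 97 110 121 129 133 133 129 121 110 97 83 66 49 31 12 0 0
0 0 0 18 35 51 66 80 91 101 107 110 110 107 101 91 80 66 51 35 18 0 0 0
0 0 0 4 20 35 49 61 71 80 85 88 88 85 80 71 61 49 35 20 4 0 0 0
0 0 0 0 4 18 31 42 51 59 64 66 66 64 59 51 42 31 18 4 0 0 0 0
0 0 0 0 0 0 12 22 31 37 42 44 44 42 37 31 22 12 0 0 0 0 0 0
0 0 0 0 0 0 0 2 10 16 20 22 22 20 16 10 2 0 0 0 0 0 0 0
0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0
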