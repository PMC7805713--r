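id,age,gender,group
1,10,M,TD
2,4,F,TD
3,5,F,TD
4,11,F,TD
5,9,M,TD
6,10,F,TD
7,9,M,TD
8,5,M,TD
9,5,F,TD
10,5,M,TD
11,5,M,TD
12,5,M,TD
13,9,M,TD
14,7,M,ASD
15,8,M,ASD
16,10,M,ASD
17,8,M,ASD
18,8,M,ASD
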