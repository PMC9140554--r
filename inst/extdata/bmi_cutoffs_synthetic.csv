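age_years,sex,underweight_cutoff,overweight_cutoff,obese_cutoff
2,boy,14.1,18.4,20.1
3,boy,13.8,17.9,19.6
4,boy,13.5,17.6,19.3
5,boy,13.3,17.4,19.3
6,boy,13.2,17.6,19.8
7,boy,13.1,17.9,20.6
8,boy,13.2,18.4,21.6
9,boy,13.4,19.1,22.8
10,boy,13.6,19.8,24.0
11,boy,13.9,20.6,25.1
12,boy,14.3,21.2,26.0
13,boy,14.8,21.9,26.8
14,boy,15.4,22.6,27.6
15,boy,15.9,23.3,28.3
16,boy,16.4,23.9,28.9
17,boy,16.7,24.5,29.4
18,boy,17.0,25.0,30.0
2,girl,13.9,18.0,19.8
3,girl,13.6,17.6,19.4
4,girl,13.3,17.3,19.1
5,girl,13.1,17.1,19.2
6,girl,13.0,17.3,19.7
7,girl,13.0,17.8,20.5
8,girl,13.1,18.3,21.6
9,girl,13.3,19.1,22.8
10,girl,13.6,19.9,24.1
11,girl,14.0,20.7,25.4
12,girl,14.5,21.7,26.7
13,girl,15.0,22.6,27.8
14,girl,15.6,23.3,28.6
15,girl,16.1,23.9,29.1
16,girl,16.5,24.4,29.4
17,girl,16.8,24.7,29.7
18,girl,17.0,25.0,30.0
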