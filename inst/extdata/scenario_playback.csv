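no,actual,predicted,lighting,confidence
1,walking,walking,well_lit,98.0
2,sitting,sitting,well_lit,97.5
3,sitting,sitting,well_lit,98.2
4,lying_in_bed,sleeping,poorly_lit,89.3
5,standing,standing,well_lit,99.7
6,lying_in_bed,lying_in_bed,semi_lit,87.9
7,sleeping,lying_in_bed,semi_lit,88.6
8,standing,standing,well_lit,99.1
9,sleeping,sleeping,poorly_lit,85.4
10,walking,walking,well_lit,93.6
11,lying_in_bed,lying_in_bed,well_lit,94.2
12,standing,standing,well_lit,99.3
13,walking,walking,poorly_lit,96.0
14,sitting,sitting,well_lit,98.5
15,sleeping,sleeping,well_lit,91.0
16,fallen_on_ground,fallen_on_ground,well_lit,99.8
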