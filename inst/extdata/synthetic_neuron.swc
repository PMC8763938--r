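# synthetic pyramidal-neuron morphology (toy example, not a reconstruction)
# columns: id type x y z radius parent ; types: 1 soma, 3 basal, 4 apical
1 1 0 0 0 8 -1
2 4 0 40 0 1.5 1
3 4 0 80 0 1.2 2
4 4 -30 120 0 1.0 3
5 4 30 120 0 1.0 3
6 4 -30 170 0 0.8 4
7 4 30 180 0 0.8 5
8 3 -40 -30 0 1.2 1
9 3 -80 -60 0 1.0 8
10 3 40 -30 0 1.2 1
11 3 80 -55 0 1.0 10
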