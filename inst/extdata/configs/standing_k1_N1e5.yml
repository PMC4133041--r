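# As standing_k1_N1e4 but a tenfold larger initial population.
N0: 100000
r: 0.01
s: 0.02
u: 0.0
p0: 1.0e-5
n_successes: 5000
record: curves
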