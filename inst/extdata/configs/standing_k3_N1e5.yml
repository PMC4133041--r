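# Three standing copies in a large, slowly declining population.
N0: 100000
r: 0.005
s: 0.02
u: 0.0
p0: 3.0e-5
n_successes: 5000
record: curves
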