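# Rescue by recurrent mutation only; U-curve stretched right.
N0: 10000
r: 0.01
s: 0.02
u: 1.0e-5
p0: 0.0
n_successes: 2000
record: curves
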