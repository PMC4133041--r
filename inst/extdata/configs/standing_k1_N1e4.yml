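# Rescue from one standing copy in a moderately sized population.
N0: 10000
r: 0.01
s: 0.02
u: 0.0
p0: 1.0e-4
n_successes: 5000
record: curves
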