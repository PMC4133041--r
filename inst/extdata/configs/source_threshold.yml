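# Standing variation vs new mutation at the p0 = u/r threshold.
N0: 10000
r: 0.00333
s: 0.01
u: 1.0e-6
p0: 3.0e-4
n_runs: 20000
record: none
stop_at: establishment
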