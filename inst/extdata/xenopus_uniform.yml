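# Embryo-style strong-firing configuration: one 3000-kb chromosome,
# uniformly placed potential origins re-drawn each run.
# Units: kb, min.
genome_source: uniform
length_kb: 3000
rho0: 0.70
v: 0.6
kon: 3.0e-3
ndt: 187
tau_load: 3
n_runs: 100
bin_width: 0.5
seed: 1
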