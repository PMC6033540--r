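# Yeast-scale configuration over the bundled synthetic origin map
# (829 origins on 16 chromosomes; stand-in for a database export).
# Units: kb, min.
genome_source: file
origin_file: yeast_synthetic_origins.tsv
categories: [Confirmed, Likely, Dubious]
v: 1.5
kon: 3.6e-3
ndt: 143
tau_load: 10
n_runs: 60
bin_width: 1
seed: 1
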