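# Example configuration for the command-line surface.  The alignment is a
# synthetic fixture bundled with the package (see example_synthetic.fasta).
model: NR
alignment: example_synthetic.fasta
format: fasta
seed: 1
K: 4
n_iter: 20000
burnin: 0.25
thin: 10
out_dir: phyloroot_out
priors:
  brlen_mean: 0.1
  sigma_n_mean: 0.25
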