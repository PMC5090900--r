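msa: alignment.fasta
msa_format: fasta
habitat: habitat.tsv
hydro: hydrocarbons.tsv
blot: blot.tsv
reference_id: marine1
scan:
  ingroup:
  - marine1
  - marine2
  mode: strict
  target: fresh6
tree:
  k: 2.0
output_dir: aartools-output
seed: 20.0
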