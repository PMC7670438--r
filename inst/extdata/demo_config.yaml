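# Demo configuration: every value is a pipeline default, so this file runs
# unedited.  Override any block to change the run.
seed: 1
simulate:
  n_genes: 6
  gene_len_codons: 300
  n_reads: 2000
screen:
  word_size: 28
  e_value_threshold: 1.0e-10
  min_identity: 60
  min_len: 50
  microbiome_identity: 98
dating:
  loss_policy: strict
expression:
  min_perfect: 60
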