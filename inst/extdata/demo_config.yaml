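# Demo run: a 1.5 Mb toy genome with 6 planted piRNA clusters, and two
# tissues (ovary-like, semen-like) with two replicate libraries each.
seed: 42
genome:
  genome_length: 1500000
  n_clusters: 6
  cluster_size: [1000, 4000]
tissues:
  ovary:
    n_reads: 5000
    n_replicates: 2
  semen:
    n_reads: 5000
    n_replicates: 2
pairs:
  - [ovary, semen]
de:
  fdr_max: 0.01
  fc_min: 5
  min_count: 5
cluster:
  max_gap: 1000
  min_reads: 35
  min_density: 10
  merge_dist: 1000
  min_len: 200
write_alignments: true
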