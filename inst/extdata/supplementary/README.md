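# Benchmark drop-in directory

The published benchmark files are journal supplementary material and are not
redistributed here. To run the published comparison, place in this directory
(or in the directory named by `options(bpsfinder.supplementary_dir = ...)`):

- `dataset_s1.fa` — 42 experimentally verified introns, FASTA with `bp=`
  branch-site headers (3'ss-relative negative positions);
- `dataset_s2.fa` — 88 manually curated introns, same format;
- `table_s4.tsv`, `table_s5.tsv`, `table_s6.tsv` — 4x7 relative-frequency
  matrices, TSV with a `base` column (A/C/G/T) and `pos1`..`pos7` columns.

`bpsfinder::supplementary_status()` reports what is present;
`bpsfinder::benchmark_accuracy()` runs the protocol.
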