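tree: synthetic_tree.nwk
annotations: synthetic_nodes.tsv
counts: synthetic_counts.tsv
metrics: synthetic_metrics.tsv
fasta: synthetic_orc1.faa
motifs: synthetic_motifs.yaml
ref: Hsap
out_dir: orcEvo-demo-out
seed: 1
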