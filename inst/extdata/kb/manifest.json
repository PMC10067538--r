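{
  "c1_encoding": "c1_encoding.tsv",
  "c2_alignment": "c2_alignment.tsv",
  "c3_layout": "c3_layout.tsv",
  "c4_partition": "c4_partition.tsv",
  "c5_arrangement": "c5_arrangement.tsv",
  "c6_interactivity": "c6_interactivity.tsv"
}
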