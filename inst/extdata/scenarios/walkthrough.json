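{
  "files": [
    {
      "format": "bed",
      "label": "BED1",
      "assembly": "hg38",
      "attributes": [{"kind": "categorical", "label": "gene_class"}]
    },
    {
      "format": "vcf",
      "label": "VCF1",
      "assembly": "hg38",
      "attributes": [{"kind": "categorical", "label": "variant_type"}]
    },
    {
      "format": "bigwig",
      "label": "BIGWIG1",
      "assembly": "hg38",
      "attributes": [{"kind": "quantitative", "label": "signal"}]
    }
  ],
  "task": "compare"
}
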