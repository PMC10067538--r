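{
  "files": [
    {
      "format": "vcf",
      "label": "VCF1",
      "assembly": "hg38",
      "attributes": [{"kind": "categorical", "label": "variant_class"}],
      "extent": "point",
      "density": "sparse",
      "connection": "none"
    }
  ],
  "task": "identify"
}
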