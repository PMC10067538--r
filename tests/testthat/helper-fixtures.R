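# shared fixtures built in code

kb_default <- load_knowledge_base()

walkthrough_scenario <- function() {
  scenario(list(
    genomic_file("bed", "BED1",
                 attributes = list(attribute_descriptor("categorical", "gene_class"))),
    genomic_file("vcf", "VCF1",
                 attributes = list(attribute_descriptor("categorical", "variant_type"))),
    genomic_file("bigwig", "BIGWIG1",
                 attributes = list(attribute_descriptor("quantitative", "signal")))
  ), task = "compare")
}

single_file_scenario <- function(format = "bigwig", kind = "quantitative",
                                 task = "identify", ...) {
  scenario(genomic_file(format, attributes = list(attribute_descriptor(kind)), ...),
           task = task)
}

# independent brute-force scorer used as ranking oracle (kept deliberately
# naive: explicit loops, no shared code with the package internals)
oracle_rank <- function(cells, input) {
  scores <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    dot <- 0; nu <- 0; nv <- 0
    for (j in seq_len(ncol(cells))) {
      dot <- dot + cells[i, j] * input[j]
      nu <- nu + cells[i, j]^2
      nv <- nv + input[j]^2
    }
    scores[i] <- dot / (sqrt(nu) * sqrt(nv))
  }
  ord <- order(-scores)
  list(option = rownames(cells)[ord], score = scores[ord])
}

random_pm1_matrix <- function(nr, nc) {
  m <- matrix(sample(c(1L, -1L), nr * nc, replace = TRUE), nr, nc)
  rownames(m) <- paste0("r", seq_len(nr))
  colnames(m) <- paste0("c", seq_len(nc))
  m
}
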