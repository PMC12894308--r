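`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal count_table around a bare matrix.
toy_table <- function(counts, treatments = NULL) {
  treatments <- treatments %||% rep("A", ncol(counts))
  count_table(counts,
              metadata = data.frame(sample_id = colnames(counts),
                                    treatment = treatments))
}
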