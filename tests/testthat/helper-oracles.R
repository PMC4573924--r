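# shared test helpers: quick constructors and independent oracles

make_calls <- function(pos, observed_pct, depth = 2000, gene = "GENE",
                       chrom = "chr1", ref = "A", alt = "G", ...) {
  variant_calls(data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
    gene = gene, observed_pct = observed_pct, depth = depth, ...,
    stringsAsFactors = FALSE))
}

# textbook Pearson correlation, written out from the definition so it is
# independent of stats::cor
pearson_by_hand <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# brute-force template-sampling oracle for the mixture expectation:
# draw n_templates templates choosing a component with probability
# proportional to w * c, then a variant allele with probability f/100
mixture_oracle <- function(w, cw, f, n_templates) {
  pick <- w * cw
  stopifnot(sum(pick) > 0)
  counts <- as.vector(stats::rmultinom(1, n_templates, pick / sum(pick)))
  alt <- sum(stats::rbinom(length(counts), counts, f / 100))
  100 * alt / n_templates
}

# brute-force confusion-matrix enumeration over per-sample statuses
confusion_by_hand <- function(ref_pos, test_pos) {
  c(TP = sum(ref_pos & test_pos), FP = sum(!ref_pos & test_pos),
    TN = sum(!ref_pos & !test_pos), FN = sum(ref_pos & !test_pos))
}
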