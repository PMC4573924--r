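test_that("perfect agreement and total miss score as expected, with brute-force counts", {
  ref <- reference_results(data.frame(
    sample_id = rep(sprintf("S%02d", 1:10), each = 2),
    gene = rep(c("KRAS", "EGFR"), 10),
    status = c(rbind(ifelse(1:10 <= 6, "positive", "negative"), "negative"))))
  pos_samples <- sprintf("S%02d", 1:6)
  calls <- variant_calls(data.frame(sample_id = pos_samples, chrom = "chr12",
    pos = 25398284, ref = "C", alt = "A", gene = "KRAS", observed_pct = 30,
    depth = 1500, quality = 4000, strand_bias = 0.6))
  conc <- score_concordance(calls, ref, genes = c("KRAS", "EGFR"))
  expect_equal(conc$sensitivity_pct, 100)
  expect_equal(conc$specificity_pct, 100)
  # all test samples negative
  none <- score_concordance(calls[0, ], ref, genes = c("KRAS", "EGFR"))
  expect_equal(none$sensitivity_pct, 0)
  expect_equal(none$specificity_pct, 100)
  expect_equal(none$counts, confusion_by_hand(
    ref_pos = c(rep(TRUE, 6), rep(FALSE, 4)), test_pos = rep(FALSE, 10)))
})

test_that("concordance on a random synthetic cohort matches exhaustive enumeration", {
  set.seed(91)
  n <- 200
  ids <- sprintf("C%03d", seq_len(n))
  ref_pos <- runif(n) < 0.4
  test_pos <- ifelse(ref_pos, runif(n) < 0.9, runif(n) < 0.05)
  ref <- reference_results(data.frame(sample_id = ids, gene = "BRAF",
    status = ifelse(ref_pos, "positive", "negative")))
  calls <- variant_calls(data.frame(sample_id = ids[test_pos],
    chrom = "chr7", pos = 140453136, ref = "T", alt = "A", gene = "BRAF",
    observed_pct = 25, depth = 1500, quality = 4000, strand_bias = 0.6))
  conc <- score_concordance(calls, ref, genes = "BRAF", samples = ids)
  expect_equal(conc$counts, confusion_by_hand(ref_pos, test_pos))
  # aggregates always recompute from the labels
  expect_equal(conc$sensitivity_pct,
    100 * sum(conc$table$label == "TP") /
      sum(conc$table$label %in% c("TP", "FN")))
  expect_equal(conc$specificity_pct,
    100 * sum(conc$table$label == "TN") /
      sum(conc$table$label %in% c("TN", "FP")))
  # every unit gets exactly one label
  expect_equal(sum(conc$counts), n)
})

test_that("policy gating turns a sub-threshold call into a false negative", {
  ref <- reference_results(data.frame(sample_id = c("A", "B"), gene = "EGFR",
    status = c("positive", "negative")))
  low <- variant_calls(data.frame(sample_id = "A", chrom = "chr7",
    pos = 55259515, ref = "T", alt = "G", gene = "EGFR",
    observed_pct = 3.5, depth = 1400, quality = 4000, strand_bias = 0.6))
  conc <- score_concordance(low, ref, genes = "EGFR")
  expect_equal(unname(conc$counts["FN"]), 1L)
  # explicit roster: a reference sample missing from it is an error
  expect_error(score_concordance(low, ref, genes = "EGFR", samples = "A"),
    "B")
})

test_that("hgvs-level scoring requires the coding change to match", {
  ref <- reference_results(data.frame(sample_id = "A", gene = "EGFR",
    status = "positive", hgvs_c = "c.2573T>G"))
  right <- variant_calls(data.frame(sample_id = "A", chrom = "chr7",
    pos = 55259515, ref = "T", alt = "G", gene = "EGFR", observed_pct = 30,
    depth = 1400, quality = 4000, strand_bias = 0.6, hgvs_c = "c.2573T>G"))
  wrong <- right; wrong$hgvs_c <- "c.2369C>T"
  expect_equal(unname(score_concordance(right, ref, genes = "EGFR",
    mode = "hgvs_level")$counts["TP"]), 1L)
  expect_equal(unname(score_concordance(wrong, ref, genes = "EGFR",
    mode = "hgvs_level")$counts["FN"]), 1L)
})

test_that("frequency correlation is symmetric, shift invariant, and matches the formula", {
  a <- make_calls(c(100, 200, 300, 400), c(10, 20, 40, 70))
  b <- make_calls(c(100, 200, 300, 400), c(12, 18, 45, 66))
  expect_equal(correlate_frequencies(a, a), 1)
  expect_equal(correlate_frequencies(a, b), correlate_frequencies(b, a))
  b_shift <- b; b_shift$observed_pct <- b$observed_pct + 5
  a_shift <- a; a_shift$observed_pct <- a$observed_pct + 5
  expect_equal(correlate_frequencies(a_shift, b_shift,
    join = "intersection"), correlate_frequencies(a, b,
    join = "intersection"), tolerance = 1e-12)
  expect_equal(correlate_frequencies(a, b),
    pearson_by_hand(a$observed_pct, b$observed_pct), tolerance = 1e-12)
  # disjoint variant sets under union_zero_fill: hand evaluation
  da <- make_calls(c(1, 2), c(30, 30))
  db <- make_calls(c(3, 4), c(30, 30))
  expect_equal(correlate_frequencies(da, db),
    pearson_by_hand(c(30, 30, 0, 0), c(0, 0, 30, 30)))
  expect_error(correlate_frequencies(a[1:2, ], b[1:2, ],
    join = "intersection"), "at least 3")
  flat <- make_calls(c(100, 200, 300), c(10, 10, 10))
  expect_error(correlate_frequencies(flat, flat), "degenerate")
})

test_that("replicate pairs simulated at depth 2000 correlate above 0.98", {
  truth <- mixture_profile(
    validation_profiles("frozen")[validation_profiles("frozen")$line !=
      "PLACENTA", ], equal_mix())
  cfg <- simulator_config(seed = 55, preset = "frozen")
  rs <- simulate_runs(truth, cfg, 10)
  r <- vapply(1:5, function(i) correlate_frequencies(
    rs[[2 * i - 1]]$calls, rs[[2 * i]]$calls), numeric(1))
  expect_true(all(r > 0.98))
})

test_that("artifact rules fire independently and only when their predicate holds", {
  amp <- panel_amplicons()
  maf <- maf_annotations()
  # high-MAF germline SNP (rs1050171) and end-of-amplicon CSF1R position
  calls <- variant_calls(data.frame(
    chrom = c("chr7", "chr5", "chr1", "chr10"),
    pos = c(55249063, 149433597, 999, 89711834),
    ref = c("G", "C", "A", "A"), alt = c("A", "T", "G", "AT"),
    gene = c("EGFR", "CSF1R", "NOWHERE", "PTEN"),
    observed_pct = 45, depth = 1500, quality = 4000, strand_bias = 0.6))
  ctx <- data.frame(chrom = "chr10", pos = 89711834,
    context = "GGTACGTGATAAAAATCGATG")  # A run of length 5 right of center
  ann <- flag_artifacts(calls, contexts = ctx, amp = amp, maf = maf)
  cls <- function(pos) sort(ann$class[ann$pos == pos])
  expect_true("HIGH_MAF_SNP" %in% cls(55249063))
  expect_true("END_OF_AMPLICON" %in% cls(149433597))
  expect_true("OFF_TARGET" %in% cls(999))
  expect_true("HOMOPOLYMER" %in% cls(89711834))
  # dropping the MAF source disables only that class
  ann2 <- flag_artifacts(calls, contexts = ctx, amp = amp, maf = NULL)
  expect_false(any(ann2$class == "HIGH_MAF_SNP"))
  expect_true(any(ann2$class == "HOMOPOLYMER"))
  # a mid-amplicon variant is not an edge artifact; a short run is no
  # homopolymer
  mid <- variant_calls(data.frame(chrom = "chr7", pos = 140453136,
    ref = "T", alt = "A", gene = "BRAF", observed_pct = 20, depth = 1000))
  ctx_short <- data.frame(chrom = "chr7", pos = 140453136,
    context = "ACGTACGTACTGCATGCATGC")
  ann3 <- flag_artifacts(mid, contexts = ctx_short, amp = amp, maf = maf)
  expect_equal(nrow(ann3), 0L)
})

test_that("blacklisting flags exact keys only and suppression hides but keeps them", {
  bl <- artifact_blacklist()
  calls <- variant_calls(data.frame(
    chrom = c("chr7", "chr7", "chr4"), pos = c(55249063, 55249063, 1807894),
    ref = c("G", "G", "G"), alt = c("A", "T", "A"),
    gene = c("EGFR", "EGFR", "FGFR3"),
    observed_pct = c(45, 10, 50), depth = 1500))
  out <- apply_blacklist(calls, bl)
  expect_match(out$filters[1], "BLACKLIST:HIGH_MAF_SNP")
  expect_equal(out$filters[2], "")  # same position, different alt
  expect_match(out$filters[3], "BLACKLIST")
  rep <- reportable(out)
  expect_equal(nrow(rep), 1L)
  expect_equal(nrow(out), 3L)
  expect_identical(apply_blacklist(calls, bl[0, ]), calls)
})
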