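test_that("variant classification follows allele lengths and rejects inconsistency", {
  expect_equal(variant_type(c("A", "AC", "ACTT", "A"), c("G", "GT", "A", "ATT")),
    c("SNV", "MNV", "DEL", "INS"))
  expect_error(variant_key("chr1", 10, "A", "G", "X", vtype = "DEL"),
    "inconsistent")
  expect_error(variant_key("chr1", 0, "A", "G", "X"), "1-based")
  expect_error(variant_key("chr1", 10, "A", "A", "X"), "differ")
})

test_that("call tables enforce frequency, depth and strand-bias contracts", {
  ok <- make_calls(100, 25, depth = 1000, alt_depth = 250)
  expect_s3_class(ok, "vc_calls")
  expect_error(make_calls(100, 101), "\\[0, 100\\]")
  expect_error(make_calls(100, 25, depth = 100, alt_depth = 150), "exceeds")
  # observed_pct must agree with alt_depth/depth within 0.05
  expect_error(make_calls(100, 30, depth = 1000, alt_depth = 250),
    "inconsistent")
  expect_error(make_calls(100, 25, strand_bias = 0.3), "0.5")
})

test_that("TSV and VCF dialects of the same calls round-trip and agree field-for-field", {
  calls <- variant_calls(data.frame(
    sample_id = "s1",
    chrom = c("chr7", "chr12", "chr3"), pos = c(140453136, 25398281, 41266134),
    ref = c("T", "G", "ACTT"), alt = c("A", "A", "A"),
    gene = c("BRAF", "KRAS", "CTNNB1"),
    observed_pct = c(18.5, 9.6, 11.5), depth = c(1200L, 1500L, 900L),
    alt_depth = c(222L, 144L, NA), quality = c(4500, 310, 2000),
    strand_bias = c(0.62, 0.55, NA), filters = c("", "", "")))
  tsv <- tempfile(fileext = ".tsv"); vcf <- tempfile(fileext = ".vcf")
  write_calls_tsv(calls, tsv)
  write_calls_vcf(calls, vcf)
  from_tsv <- read_calls(tsv, sample_id = "s1")
  from_vcf <- read_calls(vcf, sample_id = "s1")
  expect_equal(as.data.frame(from_tsv), as.data.frame(calls))
  for (col in c("chrom", "pos", "ref", "alt", "gene", "vtype", "depth",
      "alt_depth", "quality", "strand_bias", "filters"))
    expect_equal(from_vcf[[col]], calls[[col]], info = col)
  expect_equal(from_vcf$observed_pct, calls$observed_pct, tolerance = 1e-9)
  # a VCF fraction of 0.25 at depth 1000 converts to percent
  v2 <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t100\t.\tA\tG\t50\tPASS\tAF=0.25;DP=1000"), v2)
  got <- read_calls(v2, dialect = "vcf")
  expect_equal(got$observed_pct, 25)
  expect_equal(got$depth, 1000L)
  # multi-allelic records are split
  v3 <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t100\t.\tA\tG,T\t50\tPASS\tAF=0.25,0.1;DP=1000"), v3)
  got3 <- read_calls(v3, dialect = "vcf")
  expect_equal(nrow(got3), 2L)
  expect_equal(got3$alt, c("G", "T"))
  expect_equal(got3$observed_pct, c(25, 10))
})

test_that("empty and malformed call inputs are handled explicitly", {
  f <- tempfile(fileext = ".tsv")
  writeLines("chrom\tpos\tref\talt\tgene\tobserved_pct\tdepth", f)
  expect_warning(empty <- read_calls(f), "no call records")
  expect_equal(nrow(empty), 0L)
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt\tgene\tobserved_pct\tdepth",
    "chr1\t100\tA\tG\tX\t10\t500", "chr1\tnot_a_pos\tA\tG\tX\t10\t500"), bad)
  expect_error(suppressWarnings(read_calls(bad)), "line 2")
  nofreq <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t100\t.\tA\tG\t50\tPASS\tDP=1000"), nofreq)
  expect_error(read_calls(nofreq), "AF and DP")
})

test_that("line profile tables validate copy state, range and uniqueness", {
  base <- data.frame(line = "L1", chrom = "chr1", pos = 100, ref = "A",
    alt = "G", gene = "X", freq_pct = 52.4, copy_state = "normal")
  expect_s3_class(line_profiles(base), "line_profiles")
  bad_freq <- base; bad_freq$freq_pct <- 120
  expect_error(line_profiles(bad_freq), "\\[0, 100\\]")
  bad_state <- base; bad_state$copy_state <- "hemizygous"
  expect_error(line_profiles(bad_state), "unknown copy_state")
  del_with_freq <- base; del_with_freq$copy_state <- "hom_deletion"
  expect_error(line_profiles(del_with_freq), "hom_deletion")
  dup <- rbind(base, base)
  expect_error(line_profiles(dup), "duplicate locus")
})

test_that("BED amplicons are read 0-based half-open, sorted, headers skipped, and round-trip", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("track name=test", "chr7\t140453200\t140453300\tA2",
    "chr7\t140453100\t140453200\tA1", "chr1\t10\t50\tB1"), f)
  amp <- read_amplicons(f)
  expect_equal(nrow(amp), 3L)
  expect_equal(amp$start[amp$name == "A1"], 140453100L)
  expect_equal(amp$end[amp$name == "A1"], 140453200L)
  # sorted within chromosome regardless of input order
  a7 <- amp[amp$chrom == "chr7", ]
  expect_equal(a7$name, c("A1", "A2"))
  out <- tempfile(fileext = ".bed")
  write_amplicons(amp, out)
  expect_equal(as.data.frame(read_amplicons(out)), as.data.frame(amp))
  expect_error(amplicons(data.frame(chrom = "chr1", start = 50, end = 50)),
    "start < end")
})

test_that("cutoff rules round-trip losslessly through JSON", {
  rules <- cutoff_rules(list(
    derive_cutoff(mean = 1231, sd = 526, metric = "coverage",
      side = "lower", z = 1.96, confidence = 95, rounding = "integer"),
    derive_cutoff(mean = 3.65, sd = 0.45, metric = "quality_log10",
      side = "lower", z = 2.576, confidence = 99, transform = "log10",
      rounding = "signif", digits = 1)))
  f <- tempfile(fileext = ".json")
  write_cutoff_json(rules, f)
  back <- read_cutoff_json(f)
  expect_equal(back, rules)
  # empty rule set serializes to an empty JSON list and comes back empty
  f2 <- tempfile(fileext = ".json")
  write_cutoff_json(cutoff_rules(list()), f2)
  expect_length(read_cutoff_json(f2), 0L)
  expect_error(write_cutoff_json(rules, file.path(tempdir(), "nope", "x.json")),
    "cannot write")
})
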