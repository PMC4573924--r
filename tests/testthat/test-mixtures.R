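four_lines <- function(profiles) profiles[profiles$line != "PLACENTA", ]

test_that("equal four-line mix reproduces published single-carrier expectations", {
  for (type in c("frozen", "ffpe")) {
    pr <- four_lines(validation_profiles(type))
    ep <- mixture_profile(pr, equal_mix())
    # single-carrier loci: expectation is carrier frequency / 4
    ids <- variant_id(pr)
    carriers <- table(ids[pr$copy_state == "normal"])
    single <- names(carriers)[carriers == 1]
    single <- setdiff(single, variant_id(pr[pr$copy_state == "hom_deletion", ]))
    for (id in single) {
      f <- pr$freq_pct[ids == id & pr$copy_state == "normal"]
      got <- ep$expected_pct[variant_id(ep) == id]
      expect_equal(got, f / 4, tolerance = 1e-12, info = paste(type, id))
    }
  }
})

test_that("mixture expectation is the weighted mean with copy-aware template weights", {
  pr <- line_profiles(data.frame(
    line = c("A", "A", "B", "B", "C"),
    chrom = "chr1", pos = c(100, 200, 100, 300, 300),
    ref = "A", alt = "G", gene = "X",
    freq_pct = c(40, 80, 60, NA, 10),
    copy_state = c("normal", "normal", "normal", "hom_deletion", "normal")))
  mx <- mixture_spec(c("A", "B", "C"), c(0.5, 0.3, 0.2))
  ep <- mixture_profile(pr, mx)
  g <- function(pos) ep$expected_pct[ep$pos == pos]
  expect_equal(g(100), 0.5 * 40 + 0.3 * 60)            # C wild type (absent)
  expect_equal(g(200), 0.5 * 80)                        # only A carries it
  # B deleted at 300: templates only from A (wt) and C
  expect_equal(g(300), (0.2 * 10) / (0.5 + 0.2))
  # single-component mixture returns the line's own frequencies
  solo <- mixture_profile(pr[pr$line == "A", ], mixture_spec("A", 1))
  expect_equal(solo$expected_pct[solo$pos == 100], 40)
  # all components deleted at a locus is an error naming it
  del <- line_profiles(data.frame(line = c("A", "B"), chrom = "chr1",
    pos = 500, ref = "A", alt = "G", gene = "X", freq_pct = NA,
    copy_state = "hom_deletion"))
  expect_error(mixture_profile(del, mixture_spec(c("A", "B"))),
    "no template.*chr1:500")
})

test_that("loci carried at frequency 0 are emitted with expectation 0, not dropped", {
  pr <- line_profiles(data.frame(line = "A", chrom = "chr1", pos = 100,
    ref = "A", alt = "G", gene = "X", freq_pct = 0, copy_state = "normal"))
  ep <- mixture_profile(pr, mixture_spec("A", 1))
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$expected_pct, 0)
})

test_that("mixture spec validates fractions and uniqueness", {
  expect_error(mixture_spec(c("A", "A")), "unique")
  expect_error(mixture_spec(c("A", "B"), c(0.6, 0.6)), "sum to 1")
  expect_error(mixture_spec(c("A", "B"), c(1.2, -0.2)), "\\(0, 1\\]")
})

test_that("convexity: with normal copy states the expectation lies within component range", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(2:5, 1)
    f <- runif(n, 0, 100)
    w <- runif(n); w <- w / sum(w)
    pr <- line_profiles(data.frame(line = paste0("L", seq_len(n)),
      chrom = "chr1", pos = 100, ref = "A", alt = "G", gene = "X",
      freq_pct = f, copy_state = "normal"))
    e <- expected_vaf(pr, mixture_spec(paste0("L", seq_len(n)), w),
      variant_key("chr1", 100, "A", "G", "X"))
    expect_gte(e, min(f) - 1e-12)
    expect_lte(e, max(f) + 1e-12)
  }
})

test_that("copy-number invariance: a single template-contributing component fixes the expectation", {
  set.seed(7)
  for (rep in 1:10) {
    w1 <- runif(1, 0.05, 0.95)
    pr <- line_profiles(data.frame(line = c("CARRIER", "DELETED"),
      chrom = "chr9", pos = 21971153, ref = "C", alt = "T", gene = "CDKN2A",
      freq_pct = c(73.2, NA), copy_state = c("normal", "hom_deletion")))
    e <- expected_vaf(pr, mixture_spec(c("CARRIER", "DELETED"),
      c(w1, 1 - w1)), variant_key("chr9", 21971153, "C", "T", "CDKN2A"))
    expect_equal(e, 73.2, tolerance = 1e-12)
  }
})

test_that("serial dilution: identity at fraction 1, diluent-borne loci enter, dilution chains compose", {
  pr <- validation_profiles("frozen")
  placenta <- pr[pr$line == "PLACENTA", ]
  ep <- mixture_profile(four_lines(pr), equal_mix())
  expect_identical(serial_dilute(ep, placenta, 1), ep)
  half <- serial_dilute(ep, placenta, 1 / 2)
  atm <- function(p) p$expected_pct[p$pos == 108138003]
  expect_equal(atm(half), 55.8 / 2, tolerance = 1e-12)
  expect_error(serial_dilute(ep, placenta, 0), "\\(0, 1\\]")
  expect_error(serial_dilute(ep, placenta, 1.5), "\\(0, 1\\]")
  # associativity: diluting by a then b equals the three-component mixture
  # with weights (a*b, a*(1-b) ... ) -- here diluent twice, so weights
  # a*b mix and 1 - a*b diluent
  a <- 1 / 2; b <- 2 / 3
  twice <- serial_dilute(serial_dilute(ep, placenta, a), placenta, b)
  once <- serial_dilute(ep, placenta, a * b)
  m <- merge(as.data.frame(twice), as.data.frame(once),
    by = c("chrom", "pos", "ref", "alt"))
  expect_equal(m$expected_pct.x, m$expected_pct.y, tolerance = 1e-9)
})

test_that("mixture formula agrees with the template-sampling oracle", {
  set.seed(2024)
  n_templates <- 2e5
  for (rep in 1:8) {
    n <- sample(2:4, 1)
    f <- runif(n, 0, 100)
    cw <- ifelse(runif(n) < 0.15, 0, 1)
    if (all(cw == 0)) cw[1] <- 1
    f[cw == 0] <- NA
    w <- runif(n); w <- w / sum(w)
    pr <- line_profiles(data.frame(line = paste0("L", seq_len(n)),
      chrom = "chr1", pos = 100, ref = "A", alt = "G", gene = "X",
      freq_pct = f, copy_state = ifelse(cw == 0, "hom_deletion", "normal")))
    e <- expected_vaf(pr, mixture_spec(paste0("L", seq_len(n)), w),
      variant_key("chr1", 100, "A", "G", "X"))
    sim <- mixture_oracle(w, cw, ifelse(is.na(f), 0, f), n_templates)
    mc_sd <- 100 * sqrt(e / 100 * (1 - e / 100) / n_templates)
    expect_lte(abs(sim - e), max(3 * mc_sd, 1e-9))
  }
})
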