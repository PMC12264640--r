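test_that("codon counting is exact and skips N-containing codons", {
  cc <- count_codons("ATGAAATAA")
  expect_equal(unname(cc[c("ATG", "AAA", "TAA")]), c(1L, 1L, 1L))
  expect_equal(attr(cc, "total"), 3)
  expect_equal(attr(count_codons(strrep("GCT", 100)), "total"), 100)
  ccN <- count_codons("ATGANAGCTTAA")
  expect_equal(attr(ccN, "total"), 3)  # ANA uncounted
  expect_error(count_codons("ATGA"), "multiple of 3")
})

test_that("positional GC matches hand counts and the GC12 identity", {
  g <- positional_gc("GGGCCC")
  expect_equal(unname(g[c("gc1", "gc2", "gc3")]), c(1, 1, 1))
  g2 <- positional_gc("ATGGCA")  # ATG, GCA
  expect_equal(unname(g2), c(0.5, 0.5, 0.5, 0.5))
  set.seed(1)
  for (i in 1:20) {
    s <- paste(sample(genetic_code()$codon, 30, TRUE), collapse = "")
    g3 <- positional_gc(s)
    expect_equal(g3[["gc12"]], (g3[["gc1"]] + g3[["gc2"]]) / 2)
  }
  # include_stop = FALSE drops the final codon: only ATA remains
  expect_equal(positional_gc("ATAGGG", include_stop = FALSE)[["gc3"]], 0)
  expect_equal(positional_gc("ATAGGG", include_stop = TRUE)[["gc3"]], 0.5)
})

test_that("RSCU follows the family-normalised formula and conserves family size", {
  cc <- count_codons(paste0(strrep("AAA", 3), "AAG", "ATG"))
  r <- rscu(cc)
  expect_equal(r$rscu[r$codon == "AAA"], 1.5)
  expect_equal(r$rscu[r$codon == "AAG"], 0.5)
  expect_equal(r$rscu[r$codon == "ATG"], 1)  # single-codon family present
  # uniform usage within every family -> all RSCU = 1
  unif <- count_codons(paste(genetic_code()$codon, collapse = ""))
  expect_true(all(abs(rscu(unif)$rscu - 1) < 1e-12))
  # conservation: within every present family the RSCU values sum to size
  set.seed(7)
  for (i in 1:25) {
    x <- random_counts(1000 + i)
    counts <- structure(as.integer(x), names = names(x), total = sum(x),
                        class = "codon_counts")
    rt <- rscu(counts)
    sums <- tapply(rt$rscu, genetic_code()$family, sum)
    sizes <- tapply(rt$family_size, genetic_code()$family, max)
    present <- tapply(rt$count, genetic_code()$family, sum) > 0
    expect_true(all(abs(sums[present] - sizes[present]) < 1e-9))
  }
  # absent family flagged with zero RSCU
  r0 <- rscu(count_codons("ATGTAA"))
  expect_true(all(r0$rscu[r0$aa == "K"] == 0))
  expect_true(all(r0$absent[r0$aa == "K"]))
})

test_that("observed ENC hits the theoretical extremes and stays in bounds", {
  expect_equal(enc_observed(count_codons(one_codon_per_family_gene())), 20)
  unif <- count_codons(paste(rep(genetic_code()$codon, 50), collapse = ""))
  expect_equal(enc_observed(unif), 61)
  set.seed(11)
  for (i in 1:30) {
    x <- random_counts(2000 + i)
    counts <- structure(as.integer(x), names = names(x), total = sum(x),
                        class = "codon_counts")
    e <- enc_observed(counts)
    if (!is.na(e)) expect_true(e >= 20 - 1e-9 && e <= 61 + 1e-9)
  }
  # no usable families -> undefined
  expect_true(is.na(enc_observed(count_codons("ATGTAA"))))
})

test_that("observed ENC equals the independent step-by-step oracle", {
  for (i in 1:100) {
    x <- random_counts(i)
    counts <- structure(as.integer(x), names = names(x), total = sum(x),
                        class = "codon_counts")
    got <- enc_observed(counts)
    want <- oracle_enc(x)
    if (is.na(want)) expect_true(is.na(got)) else
      expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("expected ENC matches the closed form and its symmetry", {
  expect_equal(enc_expected(0.5), 60.5)
  expect_equal(enc_expected(0), 31)
  expect_equal(enc_expected(1), 32)
  g <- seq(0.05, 0.95, by = 0.05)
  expect_equal(enc_expected(g) - g, enc_expected(1 - g) - (1 - g))
  expect_error(enc_expected(1.2), "fraction")
  expect_error(enc_expected(-0.1), "fraction")
})

test_that("ENC ratio arithmetic and sign convention", {
  expect_equal(enc_ratio(55, 55), 0)
  expect_equal(enc_ratio(60, 57), 0.05)
  expect_true(enc_ratio(50, 55) < 0)
  expect_error(enc_ratio(0, 10), "positive")
})

test_that("CAI is a geometric mean with length invariance", {
  w <- rep(NA_real_, 64)
  names(w) <- genetic_code()$codon
  w[c("AAA", "TTA")] <- c(1, 0.5)
  w["GCT"] <- 1
  expect_equal(cai(count_codons("AAATTA"), w), sqrt(0.5))
  expect_equal(cai(count_codons(strrep("GCTAAA", 20)), w), 1)
  # invariant to gene length at fixed codon proportions
  expect_equal(cai(count_codons(strrep("AAATTA", 1)), w),
               cai(count_codons(strrep("AAATTA", 25)), w))
  expect_true(is.na(cai(count_codons("ATGTAA"), w)))
})

test_that("CAI weights from a reference are RSCU scaled to the family maximum", {
  ref <- count_codons(paste0(strrep("AAA", 3), "AAG", strrep("GGT", 2),
                             strrep("GGA", 2)))
  w <- cai_weights(ref)
  expect_equal(unname(w[["AAA"]]), 1)
  expect_equal(unname(w[["AAG"]]), 1 / 3)
  expect_equal(unname(w[["GGT"]]), 1)
  expect_true(is.na(w[["ATG"]]))   # single-codon family excluded
  expect_true(is.na(w[["TAA"]]))   # stop excluded
  expect_true(is.na(w[["GGC"]]))   # unobserved in reference -> undefined
})

test_that("PR2 coordinates come from fourfold families only", {
  centre <- count_codons(paste(c("GTA", "GTT", "GTG", "GTC"), collapse = ""))
  expect_equal(unname(pr2_point(centre)[c("pr2_x", "pr2_y")]), c(0.5, 0.5))
  skew <- count_codons(paste(rep(c("GTA", "GTT", "GTT", "GTT",
                                   "GTG", "GTG", "GTG", "GTC"), 5),
                             collapse = ""))
  expect_equal(unname(pr2_point(skew)[["pr2_x"]]), 0.75)
  expect_equal(unname(pr2_point(skew)[["pr2_y"]]), 0.25)
  # twofold-family codons do not move the point
  with2 <- count_codons(paste(c(rep(c("GTA", "GTT", "GTG", "GTC"), 3),
                                rep("AAA", 20), rep("TTC", 20)),
                              collapse = ""))
  expect_equal(unname(pr2_point(with2)[c("pr2_x", "pr2_y")]), c(0.5, 0.5))
  # undefined when a denominator is zero
  only_at <- count_codons(strrep("GTAGTT", 5))
  expect_true(is.na(pr2_point(only_at)[["pr2_x"]]))
})

test_that("synonymous GC3s excludes Met, Trp and stop codons", {
  # ATG (G third) and TGG excluded; GTA/GTT thirds are A/T -> gc3s 0
  cc <- count_codons(paste(c("ATG", "TGG", "GTA", "GTT"), collapse = ""))
  expect_equal(synonymous_gc3(cc), 0)
  cc2 <- count_codons(paste(c("GTG", "GTC", "AAA"), collapse = ""))
  expect_equal(synonymous_gc3(cc2), 2 / 3)
})
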