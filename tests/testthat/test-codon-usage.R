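partition <- build_family_partition()

test_that("standard-code family partition has the expected structure", {
  expect_equal(partition$Ns, 2)
  expect_equal(partition$K2, 12)
  expect_equal(partition$K3, 1)
  expect_equal(partition$K4, 8)
  # uniform-usage ceiling forced by the family structure
  expect_equal(partition$Ns + 2 * partition$K2 + 3 * partition$K3 +
                 4 * partition$K4, 61)
  expect_error(build_family_partition(999), "unknown genetic code")
})

test_that("RSCU matches hand values and family sums equal family size", {
  r <- rscu(c(TTT = 3, TTC = 1), partition)
  expect_equal(r[c("TTT", "TTC")], c(TTT = 1.5, TTC = 0.5))
  # single-codon extreme reaches family size
  g <- rscu(c(GGA = 4), partition)
  expect_equal(g[["GGA"]], 4)
  expect_equal(g[["GGC"]], 0)
  # equal counts everywhere -> all RSCU = 1
  uni <- rscu(stats::setNames(rep(2, 61), partition$sense_codons), partition)
  expect_true(all(uni == 1))
  # family sums are exactly k_a on random tables; NA only for empty families
  set.seed(42)
  for (i in 1:10) {
    cc <- random_count_table()
    r <- rscu(cc, partition)
    for (fam in partition$families) {
      vals <- r[fam$codons]
      if (all(is.na(vals))) {
        expect_equal(sum(cc[fam$codons]), 0)
      } else {
        expect_equal(sum(vals), as.numeric(fam$m), tolerance = 1e-14)
      }
    }
  }
})

test_that("family homozygosity F_CF follows the pseudocounted formula", {
  expect_equal(family_fcf(c(3, 1)), 5 / 9)
  expect_equal(family_fcf(c(0, 0)), 0.5)     # empty family floor 1/m
  expect_equal(family_fcf(c(1e6, 0)), 1, tolerance = 1e-5)  # max-bias limit
  expect_equal(family_fcf(c(5, 5)), 0.5)     # equal counts give exactly 1/m
  expect_error(family_fcf(3), "fold size")
})

test_that("ENc reaches its uniform and maximum-bias limits", {
  uniform <- stats::setNames(rep(1000L, 61), partition$sense_codons)
  expect_equal(enc(uniform, partition), 61)
  one_per_family <- stats::setNames(
    rep(0L, 61), partition$sense_codons)
  for (fam in partition$families) one_per_family[fam$codons[1]] <- 1e6
  expect_equal(enc(one_per_family, partition), 23, tolerance = 1e-3)
  expect_error(enc(c(ATG = 5, TGG = 2), partition), "empty")
})

test_that("ENc agrees with a direct loop transcription on random tables", {
  set.seed(7)
  for (i in 1:25) {
    cc <- random_count_table()
    expect_equal(enc(cc, partition), oracle_enc(cc), tolerance = 1e-12)
  }
  # matrix input gives per-row values identical to vector calls
  m <- rbind(a = random_count_table(), b = random_count_table())
  per <- enc(m, partition)
  expect_equal(per[["a"]], enc(m["a", ], partition))
})

test_that("ENc decreases as usage concentrates within families", {
  base <- stats::setNames(rep(10L, 61), partition$sense_codons)
  skew <- base
  for (fam in partition$families) {
    if (fam$m >= 2) {
      skew[fam$codons] <- 0L
      skew[fam$codons[1]] <- 10L * fam$m
    }
  }
  expect_lt(enc(skew, partition), enc(base, partition))
})

test_that("CAI weights use the family maximum with a 0.5 pseudocount", {
  w <- cai_weights(c(TTT = 10, TTC = 5), partition)
  expect_equal(w[c("TTT", "TTC")], c(TTT = 1.0, TTC = 0.5))
  w0 <- cai_weights(c(TTT = 10), partition)
  expect_equal(w0[["TTC"]], 0.05)  # 0.5 / 10
  uni <- cai_weights(stats::setNames(rep(3, 61), partition$sense_codons),
                     partition)
  expect_true(all(uni == 1))
  expect_false("ATG" %in% names(uni))  # single-codon families excluded
  expect_error(cai_weights(c(TTT = 0), partition), "empty")
})

test_that("CAI is a geometric mean, 1 iff only family-best codons are used", {
  ref <- stats::setNames(rep(1, 61), partition$sense_codons)
  ref["TTT"] <- 4; ref["TTC"] <- 1
  w <- cai_weights(ref, partition)
  # two occurrences with weights 0.25 and 1 -> sqrt(0.25)
  expect_equal(cai(c(TTC = 1, TTT = 1), w), 0.5)
  expect_equal(cai(c(TTT = 7), w), 1)
  # duplication invariance of the geometric mean
  g <- c(TTC = 3, TTT = 2, GGA = 5)
  expect_equal(cai(g, w), cai(2 * g, w))
  expect_lt(cai(c(TTC = 1), w), 1)
  expect_error(cai(c(ATG = 3), w), "no scorable codons")
})

test_that("SCUO spans [0,1] with the entropy-based hand value", {
  uniform <- stats::setNames(rep(5L, 61), partition$sense_codons)
  expect_equal(scuo(uniform, partition), 0)
  one_per_family <- stats::setNames(rep(0L, 61), partition$sense_codons)
  for (fam in partition$families) one_per_family[fam$codons[1]] <- 5L
  expect_equal(scuo(one_per_family, partition), 1)
  # one two-fold family with counts (3,1): 1 - H(0.75, 0.25)
  h <- -(0.75 * log2(0.75) + 0.25 * log2(0.25))
  expect_equal(scuo(c(TTT = 3, TTC = 1), partition), 1 - h, tolerance = 1e-4)
  set.seed(8)
  for (i in 1:10) {
    cc <- random_count_table()
    v <- scuo(cc, partition)
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(v, oracle_scuo(cc), tolerance = 1e-12)
  }
})

test_that("GC content averages per-gene percentages", {
  s <- Biostrings::DNAStringSet(c(a = "ATGC", b = "GGCC"))
  expect_equal(gc_content(s[1]), 50)
  expect_equal(gc_content(s[2]), 100)
  expect_equal(gc_content(s), 75)            # mean of per-gene values
  s2 <- Biostrings::DNAStringSet(c(a = "AT", b = "GGCCGG"))
  expect_equal(gc_content(s2), 50)           # equal gene weights
  expect_equal(gc_content(s2, pooled = TRUE), 75)  # nucleotide pooling
})
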