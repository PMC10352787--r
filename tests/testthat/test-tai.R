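rules <- wobble_rules()

test_that("wobble recognizers follow the third-base rules and special cases", {
  ggc <- recognizers("GGC", rules)
  expect_equal(ggc$anticodon, c("GCC", "ACC"))
  expect_equal(ggc$class, c("WC", "IC"))
  ggt <- recognizers("GGT", rules)
  expect_equal(ggt$anticodon, c("ACC", "GCC"))
  expect_equal(ggt$class, c("WC", "GU"))
  gga <- recognizers("GGA", rules)
  expect_equal(gga$anticodon, c("TCC", "ACC"))
  expect_equal(gga$class, c("WC", "IA"))
  ggg <- recognizers("GGG", rules)
  expect_equal(ggg$anticodon, c("CCC", "TCC"))
  expect_equal(ggg$class, c("WC", "UG"))
  # initiator/Trp restricted to Watson-Crick
  expect_equal(recognizers("ATG", rules),
               data.frame(anticodon = "CAT", class = "WC"))
  expect_equal(recognizers("TGG", rules),
               data.frame(anticodon = "CCA", class = "WC"))
  expect_error(recognizers("TGA", rules), "stop codon")
  # lysidine rule only in prokaryote mode
  pro <- wobble_rules(prokaryote = TRUE)
  ata <- recognizers("ATA", pro)
  expect_true(any(ata$anticodon == "CAT" & ata$class == "LA"))
  expect_false("LA" %in% recognizers("ATA", rules)$class)
  # every sense codon has at least one WC recognizer
  expect_true(all(vapply(unique(rules$codon), function(cd)
    "WC" %in% recognizers(cd, rules)$class, logical(1))))
})

test_that("absolute adaptiveness implements the coupling-weighted sum", {
  tg <- tgcn_table(c(ACC = 1, GCC = 2))
  m <- absolute_adaptiveness(tg, sij_weights(GU = 0.41), rules)
  expect_equal(m["GGT", "W"], 1 * 1 + 0.59 * 2)  # WC + (1-s)*wobble
  expect_equal(m["TTT", "W"], 0)                 # no recognizing copies
  # linearity in tGCN
  m2 <- absolute_adaptiveness(tgcn_table(c(ACC = 2, GCC = 4)),
                              sij_weights(GU = 0.41), rules)
  expect_equal(m2$W, 2 * m$W)
  # lysidine copies feed the L:A term only
  pro <- wobble_rules(prokaryote = TRUE)
  tg_lys <- tgcn_table(c(CAT = 5, GAT = 1), lysidine_count = 2)
  mp <- absolute_adaptiveness(tg_lys, sij_weights(LA = 0.5), pro)
  expect_equal(mp["ATG", "W"], 5)                # Met uses genomic CAT
  expect_equal(mp["ATA", "W"], 0.5 * 2)          # ATA uses lysidine copies
})

test_that("relative adaptiveness normalizes and imputes zero-W codons", {
  m <- absolute_adaptiveness(tgcn_table(c(ACC = 2, AAA = 1)), sij_weights(),
                             rules)
  r <- relative_adaptiveness(m)
  expect_equal(max(r$w), 1)
  expect_equal(r["GGT", "w"], 1)
  expect_equal(r["TTT", "w"], 0.5)
  # zero-W codons get the geometric mean of the non-zero w, and are flagged
  geo <- exp(mean(log(c(1, 0.5))))
  expect_equal(r["GCA", "w"], geo)
  expect_true(r["GCA", "substituted"])
  expect_false(r["GGT", "substituted"])
  # all-equal W -> all w = 1
  s1 <- sij_weights(GU = 1, IC = 1, IA = 1, UG = 1)
  wc_only <- tgcn_table(stats::setNames(
    rep(1, length(unique(rules$codon))), revcomp3(unique(rules$codon))))
  req <- relative_adaptiveness(absolute_adaptiveness(wc_only, s1, rules))
  expect_true(all(req$w == 1))
})

test_that("gene tAI is the geometric mean of codon w values", {
  tg <- tgcn_table(c(GAA = 4, AAA = 1))
  map <- relative_adaptiveness(absolute_adaptiveness(
    tg, sij_weights(GU = 1, IC = 1, IA = 1, UG = 1), rules))
  expect_equal(map["TTC", "w"], 1)
  expect_equal(map["TTT", "w"], 0.25)
  expect_equal(gene_tai(c(TTC = 3), map), 1)          # all-optimal gene
  expect_equal(gene_tai(c(TTT = 1), map), 0.25)       # single codon
  expect_equal(gene_tai(c(TTT = 1, TTC = 1), map), 0.5)  # sqrt(0.25 * 1)
  # self-concatenation invariance
  g <- c(TTT = 2, TTC = 5, AAA = 1)
  expect_equal(gene_tai(g, map), gene_tai(2 * g, map))
  # tGCN scale invariance propagates to tAI
  map_k <- relative_adaptiveness(absolute_adaptiveness(
    tgcn_table(c(GAA = 12, AAA = 3)),
    sij_weights(GU = 1, IC = 1, IA = 1, UG = 1), rules))
  expect_equal(gene_tai(g, map_k), gene_tai(g, map))
})

test_that("otAI preset matches a direct transcription of the model", {
  set.seed(19)
  entries <- stats::setNames(sample(0:8, 40, replace = TRUE),
                             sample(unique(rules$anticodon), 40))
  entries <- entries[entries > 0]
  tg <- tgcn_table(entries)
  map <- relative_adaptiveness(absolute_adaptiveness(tg, otai_sij(), rules))
  oracle <- oracle_adaptiveness(as.list(tg$entries), 0,
                                as.list(otai_sij()))
  expect_equal(stats::setNames(map$W, map$codon), oracle$W[map$codon],
               tolerance = 1e-12)
  expect_equal(stats::setNames(map$w, map$codon), oracle$w[map$codon],
               tolerance = 1e-12)
  for (i in 1:20) {
    g <- random_count_table()
    g <- g[g > 0]
    expect_equal(gene_tai(g, map), oracle_tai(g, oracle$w),
                 tolerance = 1e-12)
  }
})

test_that("S_ij weight vectors are validated and serializable", {
  expect_equal(sij_weights()[["WC"]], 0)
  expect_error(sij_weights(GU = 1.2), "0, 1")
  expect_error(sij_weights(XX = 0.5), "unknown interaction class")
  path <- withr::local_tempfile(fileext = ".json")
  write_sij_json(otai_sij(), path)
  back <- unlist(jsonlite::read_json(path))
  expect_equal(back[["IA"]], 0.9999)
})
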