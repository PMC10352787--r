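write_fasta <- function(records) {
  fa <- withr::local_tempfile(fileext = ".fasta",
                              .local_envir = parent.frame())
  writeLines(unlist(lapply(names(records), function(id)
    c(paste0(">", id), records[[id]]))), fa)
  fa
}

test_that("minimal valid CDS is read and counted", {
  fa <- write_fasta(list(g1 = "ATGGCTTAA"))
  cds <- read_cds_fasta(fa, min_codons = 1)
  expect_equal(length(cds), 1L)
  expect_equal(unname(Biostrings::width(cds$seqs)) / 3, 3)
  expect_equal(cds$filter_report$kept, 1L)
})

test_that("validation filters drop and count offending records", {
  fa <- write_fasta(list(
    ok = strrep("GCT", 40),
    frameshift = strrep("A", 10),
    short = "ATGGCTTAA",
    ambiguous = paste0(strrep("GCT", 30), strrep("N", 30)),
    internal_stop = paste0("ATG", "TAA", strrep("GCT", 38))
  ))
  cds <- read_cds_fasta(fa)
  r <- cds$filter_report
  expect_equal(gene_ids(cds), "ok")
  expect_equal(r$length_not_multiple_of_3, 1L)
  expect_equal(r$too_short, 1L)
  expect_equal(r$too_ambiguous, 1L)
  expect_equal(r$internal_stop, 1L)
  # filter counts + survivors account for every input record
  expect_equal(r$kept + r$length_not_multiple_of_3 + r$too_short +
                 r$too_ambiguous + r$internal_stop, r$input)
  # internal stop tolerated when strict mode is off
  lax <- read_cds_fasta(fa, strict = FALSE)
  expect_true("internal_stop" %in% gene_ids(lax))
  expect_error(read_cds_fasta(write_fasta(list(bad = "AAAA")), strict = TRUE),
               "no genes survived")
})

test_that("duplicate record ids are rejected", {
  fa <- write_fasta(list(g = strrep("GCT", 30)))
  writeLines(c(">g", strrep("GCT", 30), ">g", strrep("GCA", 30)), fa)
  expect_error(read_cds_fasta(fa), "duplicate")
})

test_that("codon counting tallies in frame, skips N codons, and is additive", {
  expect_equal(count_codons("ATGGCTGCT")[c("ATG", "GCT")],
               c(ATG = 1, GCT = 2))
  cc <- count_codons("ATGNNNGCT")
  expect_equal(cc[c("ATG", "GCT")], c(ATG = 1, GCT = 1))
  expect_equal(attr(cc, "skipped"), 1)
  # stop codons kept only on request
  expect_false("TAA" %in% names(count_codons("ATGTAA")))
  expect_equal(count_codons("ATGTAA", drop_stops = FALSE)[["TAA"]], 1)
  # additivity over genes: pooled = sum of per-gene rows
  genes <- Biostrings::DNAStringSet(c(a = "ATGGCTGCTAAA", b = "GCTTTTTTC"))
  per <- count_codons(genes, per_gene = TRUE)
  expect_equal(colSums(per), count_codons(genes), ignore_attr = TRUE)
  expect_equal(per["a", "GCT"], 2)
  expect_error(count_codons("ATGGC"), "multiple of 3")
})

test_that("tGCN parsing merges duplicates and handles isotypes", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("anticodon\tcount", "GCC\t2", "ACC\t1"), tsv)
  tg <- read_tgcn(tsv)
  expect_equal(tg$entries[c("ACC", "GCC")], c(ACC = 1, GCC = 2))

  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("GCC,1", "GCC,2"), csv)  # no header, duplicates merge
  expect_equal(read_tgcn(csv)$entries[["GCC"]], 3)

  iso <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("anticodon,count,isotype", "CAT,5,Met", "CAT,1,Ile2"), iso)
  tg2 <- read_tgcn(iso)
  expect_equal(tg2$entries[["CAT"]], 5)
  expect_equal(tg2$lysidine_count, 1)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("GXC,2", bad)
  expect_error(read_tgcn(bad), "malformed")
  writeLines("GCC,-2", bad)
  expect_error(read_tgcn(bad), "negative")
})

test_that("tGCN write/read round trip is idempotent", {
  tg <- tgcn_table(c(GCC = 2, ACC = 1, CAT = 4), lysidine_count = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tgcn(tg, path)
  back <- read_tgcn(path)
  expect_equal(back$entries, tg$entries)
  expect_equal(back$lysidine_count, tg$lysidine_count)
})

test_that("gene score tables round-trip with preserved order", {
  expect_error(write_gene_scores(numeric(0), tempfile()), "empty")
  path <- withr::local_tempfile(fileext = ".tsv")
  scores <- stats::setNames(runif(50), paste0("g", sample(50)))
  write_gene_scores(scores, path)
  back <- read_gene_scores(path)
  expect_equal(names(back), names(scores))
  expect_equal(back, scores, tolerance = 1e-12)
})

test_that("simulated FASTA round-trips with ids preserved in order", {
  sim <- small_sim(seed = 3, n_high = 20, n_background = 80)
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  back <- read_cds_fasta(paths[["fasta"]])
  expect_equal(length(back), 100L)
  expect_equal(gene_ids(back), gene_ids(sim$genes))
  tg <- read_tgcn(paths[["tgcn"]])
  expect_equal(tg$entries, sim$truth$tgcn$entries)
})
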