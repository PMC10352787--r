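# Independent, loop-based transcriptions of the defining formulas.  These
# deliberately share no code with the package implementation: plain loops
# over families, no matrix algebra, so they can serve as oracles.

oracle_partition <- function() {
  code <- Biostrings::getGeneticCode("1")
  sense <- names(code)[code != "*"]
  fams <- split(sense, code[sense])
  out <- list()
  for (aa in names(fams)) {
    cds <- fams[[aa]]
    if (length(cds) == 6) {
      for (blk in split(cds, substr(cds, 1, 2)))
        out[[length(out) + 1]] <- blk
    } else {
      out[[length(out) + 1]] <- cds
    }
  }
  out
}

oracle_rscu <- function(counts, families = oracle_partition()) {
  out <- c()
  for (cds in families) {
    o <- ifelse(cds %in% names(counts), counts[cds], 0)
    names(o) <- cds
    tot <- sum(o)
    val <- if (tot == 0) rep(NA_real_, length(cds)) else
      o / ((1 / length(cds)) * tot)
    names(val) <- cds
    out <- c(out, val)
  }
  out
}

oracle_fcf <- function(ni) {
  n <- sum(ni)
  m <- length(ni)
  tot <- 0
  for (i in seq_len(m)) tot <- tot + ((ni[i] + 1) / (n + m))^2
  tot
}

oracle_enc <- function(counts, families = oracle_partition()) {
  Ns <- sum(vapply(families, length, 0L) == 1)
  enc <- Ns
  for (m in 2:4) {
    fams_m <- families[vapply(families, length, 0L) == m]
    K <- length(fams_m)
    if (K == 0) next
    sn <- 0; snf <- 0
    for (cds in fams_m) {
      o <- ifelse(cds %in% names(counts), counts[cds], 0)
      n <- sum(o)
      if (n > 0) {
        sn <- sn + n
        snf <- snf + n * oracle_fcf(o)
      }
    }
    enc <- enc + if (sn == 0) K * m else K * sn / snf
  }
  enc
}

oracle_cai_weights <- function(ref_counts, families = oracle_partition()) {
  out <- c()
  for (cds in families) {
    if (length(cds) < 2) next
    o <- ifelse(cds %in% names(ref_counts), ref_counts[cds], 0)
    names(o) <- cds
    if (max(o) == 0) {
      w <- rep(NA_real_, length(cds))
    } else {
      w <- ifelse(o == 0, 0.5, o) / max(o)
    }
    names(w) <- cds
    out <- c(out, w)
  }
  out
}

oracle_cai <- function(gene_counts, weights) {
  logsum <- 0; tot <- 0
  for (cd in names(weights)) {
    if (is.na(weights[cd]) || !cd %in% names(gene_counts)) next
    o <- gene_counts[cd]
    logsum <- logsum + o * log(weights[cd])
    tot <- tot + o
  }
  unname(exp(logsum / tot))
}

oracle_scuo <- function(counts, families = oracle_partition()) {
  num <- 0; den <- 0
  for (cds in families) {
    m <- length(cds)
    if (m < 2) next
    o <- ifelse(cds %in% names(counts), counts[cds], 0)
    n <- sum(o)
    if (n == 0) next
    H <- 0
    for (i in seq_len(m)) {
      p <- o[i] / n
      if (p > 0) H <- H - p * log2(p)
    }
    num <- num + n * (log2(m) - H) / log2(m)
    den <- den + n
  }
  num / den
}

# Direct transcription of W_i / w_i / gene tAI for a given S vector.
oracle_adaptiveness <- function(tgcn_entries, lysidine, s, prokaryote = FALSE) {
  code <- Biostrings::getGeneticCode("1")
  sense <- names(code)[code != "*"]
  rc <- function(x) {
    comp <- chartr("ACGT", "TGCA", x)
    paste0(substr(comp, 3, 3), substr(comp, 2, 2), substr(comp, 1, 1))
  }
  copies <- function(ac) if (ac %in% names(tgcn_entries)) tgcn_entries[[ac]] else 0
  W <- numeric(0)
  for (cd in sense) {
    wc <- rc(cd)
    if (cd %in% c("ATG", "TGG")) {
      w_val <- copies(wc)
    } else {
      third <- substr(cd, 3, 3)
      wob_base <- c(T = "G", C = "A", A = "A", G = "T")[[third]]
      wob_class <- c(T = "GU", C = "IC", A = "IA", G = "UG")[[third]]
      wob <- wc; substr(wob, 1, 1) <- wob_base
      w_val <- copies(wc) + (1 - s[[wob_class]]) * copies(wob)
      if (prokaryote && cd == "ATA") w_val <- w_val + (1 - s[["LA"]]) * lysidine
    }
    W[cd] <- w_val
  }
  w <- W / max(W)
  nz <- w[w > 0]
  w[w == 0] <- exp(mean(log(nz)))
  list(W = W, w = w)
}

oracle_tai <- function(gene_counts, w) {
  logsum <- 0; tot <- 0
  for (cd in names(gene_counts)) {
    if (!cd %in% names(w)) next
    logsum <- logsum + gene_counts[cd] * log(w[cd])
    tot <- tot + gene_counts[cd]
  }
  unname(exp(logsum / tot))
}

oracle_spearman <- function(x, y) stats::cor(rank(x), rank(y))

# Random pooled codon-count table over the 61 sense codons.
random_count_table <- function(max_count = 50) {
  sense <- unlist(oracle_partition())
  stats::setNames(sample(0:max_count, length(sense), replace = TRUE), sense)
}

# Small simulated genome shared by several test files.
small_sim <- function(seed = 7, n_high = 30, n_background = 70, beta = 5) {
  simulate_genome(simulation_config(n_high = n_high,
                                    n_background = n_background,
                                    beta = beta, seed = seed))
}
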