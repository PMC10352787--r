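# Synthetic genomes with known ground truth (tRNA pool, true S_ij, selection
# strength) for validating reference selection, the fitness and GA recovery.

#' Default synthetic anticodon repertoire
#'
#' A realistic standard-code repertoire: every G34 anticodon (reading NNC by
#' Watson-Crick and NNU by G:U wobble), every C34 anticodon (NNG), every U34
#' anticodon (NNA, and NNG by U:G wobble), the Met CAT and Trp CCA
#' anticodons, and A34 (inosine) anticodons for the eight classic inosine
#' families (Ala, Pro, Thr, Val, Ser, Leu, Ile, Arg).  Restricting A34 to
#' those families mirrors real genomes and keeps every wobble class
#' identifiable.
#'
#' @return Character vector of anticodons (5'->3', wobble base first).
#' @export
default_anticodon_set <- function() {
  code <- resolve_genetic_code(1)
  sense <- sense_codons(code)
  third <- substr(sense, 3, 3)
  wc <- revcomp3(sense)
  acs <- unique(c(wc[third %in% c("C", "G", "A")]))
  inosine <- c("AGC", "AGG", "AGT", "AAC", "AGA", "AAG", "AAT", "ACG")
  sort(unique(c(acs, inosine, "CAT", "CCA")))
}

#' Simulate a tRNA gene copy number table
#'
#' Draws copy numbers (1 + Poisson(2), so 1-10ish per anticodon, matching
#' typical tGCN magnitudes) for a given anticodon repertoire, then verifies
#' decodability: under `true_s`, every synonymous family must contain at
#' least one codon with positive absolute adaptiveness.
#'
#' @param spec Either a character vector of anticodons (copies drawn
#'   randomly) or a named numeric vector of fixed copy numbers; `NULL` uses
#'   [default_anticodon_set()].
#' @param seed Optional integer seed.
#' @param true_s [sij_weights()] used for the decodability check.
#' @param rules A [wobble_rules()] table (default standard code).
#' @return A [tgcn_table()].
#' @export
simulate_tgcn <- function(spec = NULL, seed = NULL,
                          true_s = sij_weights(GU = 0.4, IC = 0.3,
                                               IA = 0.7, UG = 0.6),
                          rules = wobble_rules()) {
  if (!is.null(seed)) set.seed(seed)
  spec <- spec %||% default_anticodon_set()
  if (is.null(names(spec))) {
    copies <- 1 + stats::rpois(length(spec), 2)
    entries <- stats::setNames(copies, spec)
  } else {
    entries <- spec
  }
  tg <- tgcn_table(entries)
  map <- absolute_adaptiveness(tg, true_s, rules)
  code <- resolve_genetic_code(attr(rules, "genetic_code_id"))
  sense <- sense_codons(code)
  for (fam in split(sense, code[sense])) {
    if (all(map[fam, "W"] == 0))
      stop("anticodon spec leaves amino acid family ", code[fam[1]],
           " undecodable")
  }
  tg
}

#' Synthetic genome configuration
#'
#' Defaults define the standard study conditions: 200 highly expressed genes
#' against 1800 background genes, gene lengths uniform on 100-400 codons,
#' selection strength beta = 5, no background GC bias, and mid-range true
#' wobble penalties.
#'
#' @param n_high Number of highly expressed genes.
#' @param n_background Number of background genes.
#' @param gene_length_codons Single length or `c(min, max)` range, in codons
#'   (including start and stop).
#' @param beta Selection strength >= 0: within each amino acid family, highly
#'   expressed genes pick codon c with probability proportional to
#'   `w_true[c]^beta`.
#' @param gc_bias Background mutational GC pressure in (0, 1); 0.5 = none.
#'   Background codons are picked within-family proportionally to
#'   `(gc_bias/(1-gc_bias))^GC(codon)`.
#' @param true_s Ground-truth [sij_weights()].
#' @param tgcn_spec Passed to [simulate_tgcn()].
#' @param seed Integer seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_high = 200, n_background = 1800,
                              gene_length_codons = c(100, 400), beta = 5,
                              gc_bias = 0.5,
                              true_s = sij_weights(GU = 0.4, IC = 0.3,
                                                   IA = 0.7, UG = 0.6),
                              tgcn_spec = NULL, seed = 1) {
  stopifnot(n_high >= 1, n_background >= 0, beta >= 0,
            gc_bias > 0, gc_bias < 1)
  structure(list(n_high = n_high, n_background = n_background,
                 gene_length_codons = gene_length_codons, beta = beta,
                 gc_bias = gc_bias, true_s = sij_weights(true_s),
                 tgcn_spec = tgcn_spec, seed = seed),
            class = "simulation_config")
}

#' Simulate a genome with known codon-adaptation ground truth
#'
#' Generates coding sequences under a known tRNA pool and true S_ij vector.
#' Every gene starts with ATG, ends with a stop, and contains no internal
#' stops or ambiguous bases.  Body amino acids are drawn uniformly; highly
#' expressed genes then choose synonymous codons with probability
#' proportional to `w_true^beta` (a Boltzmann tilt of the true relative
#' adaptiveness — exactly the translational-selection assumption the S_ij
#' fitness exploits), while background genes choose codons under a purely
#' mutational GC tilt.  At `beta = 0` and `gc_bias = 0.5` the two classes are
#' distributionally identical.
#'
#' @param config A [simulation_config()].
#' @return List with `genes` (a `genome_cds_set`) and `truth` (true S_ij,
#'   the simulated [tgcn_table()], true per-codon `w`, and per-gene labels).
#' @export
simulate_genome <- function(config = simulation_config()) {
  set.seed(config$seed)
  rules <- wobble_rules(1)
  tgcn <- simulate_tgcn(config$tgcn_spec, seed = NULL,
                        true_s = config$true_s, rules = rules)
  map <- relative_adaptiveness(absolute_adaptiveness(tgcn, config$true_s, rules))
  w_true <- stats::setNames(map$w, map$codon)

  code <- resolve_genetic_code(1)
  sense <- sense_codons(code)
  fam_codons <- split(sense, code[sense])
  aa_names <- names(fam_codons)
  stops <- stop_codons(code)

  theta <- config$gc_bias / (1 - config$gc_bias)
  gc_of <- function(codons)
    vapply(strsplit(codons, ""), function(b) sum(b %in% c("G", "C")), 0L)
  probs_high <- lapply(fam_codons, function(cd) {
    p <- w_true[cd]^config$beta
    p / sum(p)
  })
  probs_bg <- lapply(fam_codons, function(cd) {
    p <- theta^gc_of(cd)
    p / sum(p)
  })

  lens_of <- function(n) {
    L <- config$gene_length_codons
    if (length(L) == 2) sample(seq(L[1], L[2]), n, replace = TRUE)
    else rep(L, n)
  }

  sample_class <- function(n_genes, probs, prefix) {
    lens <- lens_of(n_genes)
    body_len <- lens - 2L
    total <- sum(body_len)
    aas <- sample(aa_names, total, replace = TRUE)
    cod <- character(total)
    for (aa in aa_names) {
      idx <- which(aas == aa)
      if (length(idx))
        cod[idx] <- sample(fam_codons[[aa]], length(idx), replace = TRUE,
                           prob = probs[[aa]])
    }
    gene_idx <- factor(rep(seq_len(n_genes), body_len),
                       levels = seq_len(n_genes))
    bodies <- vapply(split(cod, gene_idx), paste0, collapse = "",
                     FUN.VALUE = "")
    seqs <- paste0("ATG", bodies, sample(stops, n_genes, replace = TRUE))
    stats::setNames(seqs, sprintf("%s_%04d", prefix, seq_len(n_genes)))
  }

  high <- sample_class(config$n_high, probs_high, "high")
  bg <- if (config$n_background > 0)
    sample_class(config$n_background, probs_bg, "bg") else character()

  genes <- genome_cds_set(c(high, bg), genetic_code_id = 1)
  labels <- stats::setNames(
    rep(c("high", "background"), c(length(high), length(bg))),
    c(names(high), names(bg))
  )
  truth <- list(true_s = config$true_s, tgcn = tgcn, w_true = w_true,
                labels = labels[gene_ids(genes)], config = config)
  list(genes = genes, truth = truth)
}

#' Write a simulated genome to disk
#'
#' Emits the FASTA, the tGCN TSV and a truth JSON (true S_ij, true w,
#' labels).
#'
#' @param sim Result of [simulate_genome()].
#' @param dir Output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, "genome.fasta")
  Biostrings::writeXStringSet(sim$genes$seqs, fa)
  tg <- file.path(dir, "tgcn.tsv")
  write_tgcn(sim$truth$tgcn, tg)
  truth <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(true_s = as.list(sim$truth$true_s),
         w_true = as.list(sim$truth$w_true),
         labels = as.list(sim$truth$labels)),
    truth, auto_unbox = TRUE, digits = NA)
  invisible(c(fasta = fa, tgcn = tg, truth = truth))
}
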