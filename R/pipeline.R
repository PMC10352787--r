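# End-to-end orchestration: CDS input -> reference set -> GA -> per-gene tAI.

#' Compute species-specific tAI for a genome
#'
#' Runs the full workflow: read/validate coding sequences, compute per-gene
#' improved ENc, select the lowest-ENc reference fraction, pool its RSCU,
#' infer the S_ij coupling efficiencies by genetic algorithm (maximizing the
#' codon-level Spearman correlation between reference RSCU and absolute
#' adaptiveness W_i), normalize to relative adaptiveness w_i, and score every
#' gene with the tAI geometric mean.
#'
#' @param genes Path to a CDS FASTA file, or a `genome_cds_set`.
#' @param tgcn Path to an anticodon copy-number table, or a [tgcn_table()].
#' @param ref_fraction Reference-set fraction of lowest-ENc genes (default
#'   0.05).
#' @param genetic_code Translation table id (default 1).
#' @param prokaryote Enable the lysidine L:A wobble class (default `FALSE`).
#' @param config A [ga_config()]; its `seed` governs all randomness.
#' @param seed Convenience override for `config$seed`.
#' @param sij Optional fixed [sij_weights()] (e.g. [otai_sij()]); skips the
#'   GA and scores genes directly with the supplied weights.
#' @return A `gtai_result` list: `tai` (named per-gene vector), `ga`
#'   (`ga_result` or `NULL` when `sij` was supplied), `sij`, `adaptiveness`
#'   (codon-level W/w map), `reference_ids`, `reference_rscu`, `enc`
#'   (per-gene), `filter_report` and the run configuration.
#' @examples
#' \donttest{
#' sim <- simulate_genome(simulation_config(n_high = 30, n_background = 70,
#'                                          seed = 7))
#' res <- compute_gtai(sim$genes, sim$truth$tgcn,
#'                     config = ga_config(population_size = 20,
#'                                        generations = 20, seed = 7))
#' head(res$tai)
#' }
#' @export
compute_gtai <- function(genes, tgcn, ref_fraction = 0.05, genetic_code = 1,
                         prokaryote = FALSE, config = ga_config(),
                         seed = NULL, sij = NULL) {
  if (is.character(genes)) {
    genes <- read_cds_fasta(genes, genetic_code = genetic_code)
  } else {
    genetic_code <- genes$genetic_code_id
  }
  if (is.character(tgcn)) tgcn <- read_tgcn(tgcn)
  if (!is.null(seed)) config$seed <- seed

  partition <- build_family_partition(genetic_code)
  rules <- wobble_rules(genetic_code, prokaryote = prokaryote)
  counts <- count_codons(genes, per_gene = TRUE)
  enc_values <- enc(counts, partition)

  reference <- select_reference(genes, fraction = ref_fraction,
                                partition = partition)
  ref_rscu <- reference_rscu(reference, partition)

  ga <- NULL
  if (is.null(sij)) {
    ga <- run_ga(config, tgcn, ref_rscu, rules, prokaryote = prokaryote,
                 partition = partition)
    sij <- ga$best_s
  } else {
    sij <- sij_weights(sij)
  }

  map <- relative_adaptiveness(absolute_adaptiveness(tgcn, sij, rules))
  tai <- gene_tai(counts, map)

  structure(
    list(tai = tai, ga = ga, sij = sij, adaptiveness = map,
         reference_ids = attr(reference, "reference_ids"),
         reference_rscu = ref_rscu, enc = enc_values,
         filter_report = genes$filter_report,
         config = list(ref_fraction = ref_fraction,
                       genetic_code = genetic_code,
                       prokaryote = prokaryote, ga = config)),
    class = "gtai_result"
  )
}

#' @export
print.gtai_result <- function(x, ...) {
  cat("gtai_result:", length(x$tai), "genes scored;",
      length(x$reference_ids), "reference genes\n")
  if (!is.null(x$ga))
    cat("  GA best fitness (rho RSCU~W):",
        format(x$ga$best_fitness, digits = 4), "\n")
  free <- x$sij[c("GU", "IC", "IA", "UG", "LA")]
  cat("  S_ij:", paste(names(free), format(free, digits = 3), sep = "=",
                       collapse = ", "), "\n")
  invisible(x)
}

#' Compare two per-gene score sets (optionally against abundance data)
#'
#' Computes the Spearman correlation between two gene-level indices over
#' their shared genes.  When a per-gene abundance table is supplied, both
#' indices are correlated against it and Williams' test compares the two
#' dependent correlations (which share the abundance variable).  Optionally
#' adds a repeated-subsample correlation distribution.
#'
#' @param scores_a,scores_b Named numeric vectors (gene id -> score) or
#'   two-column data frames.
#' @param abundance Optional named per-gene abundance vector.
#' @param subsample Add a [repeated_subsample_correlation()] run between
#'   `scores_a` and `scores_b` (default `FALSE`).
#' @param fraction,replicates,seed Subsampling parameters.
#' @return List with `n` (shared genes), `rho_ab`, and when abundance is
#'   given `rho_a_abundance`, `rho_b_abundance` and `williams` (t, p, df);
#'   plus `subsample_rho` when requested.
#' @export
evaluate_scores <- function(scores_a, scores_b, abundance = NULL,
                            subsample = FALSE, fraction = 0.25,
                            replicates = 1000, seed = NULL) {
  as_named <- function(x) {
    if (is.data.frame(x)) stats::setNames(as.numeric(x[[2]]), as.character(x[[1]]))
    else x
  }
  a <- as_named(scores_a)
  b <- as_named(scores_b)
  shared <- intersect(names(a), names(b))
  if (!is.null(abundance)) shared <- intersect(shared, names(abundance))
  if (length(shared) < 3) stop("fewer than 3 shared gene ids")
  out <- list(n = length(shared),
              rho_ab = spearman_rho(a[shared], b[shared]))
  if (!is.null(abundance)) {
    ab <- as_named(abundance)[shared]
    out$rho_a_abundance <- spearman_rho(a[shared], ab)
    out$rho_b_abundance <- spearman_rho(b[shared], ab)
    out$williams <- williams_test(out$rho_a_abundance, out$rho_b_abundance,
                                  out$rho_ab, n = length(shared))
  }
  if (subsample) {
    out$subsample_rho <- repeated_subsample_correlation(
      a[shared], b[shared], fraction = fraction, replicates = replicates,
      seed = seed)
  }
  out
}
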