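#' Select a putatively highly expressed reference gene set by lowest ENc
#'
#' Highly expressed genes are assumed to be the most codon-biased, so the
#' reference set is the fraction of genes with the smallest improved-ENc
#' values.  Ties at the cutoff are broken by input order, making the
#' selection deterministic; at least 5 genes are taken whenever the genome
#' has 5 or more.
#'
#' @param genes A `genome_cds_set`.
#' @param fraction Fraction of genes to select, in (0, 1] (default 0.05).
#' @param partition A [build_family_partition()]; defaults to the set's
#'   genetic code.
#' @return The selected `genome_cds_set`, with attributes `enc` (per-gene ENc
#'   of the selection) and `reference_ids`.
#' @export
select_reference <- function(genes, fraction = 0.05, partition = NULL) {
  if (length(genes) == 0) stop("empty gene set")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  partition <- partition %||% build_family_partition(genes$genetic_code_id)
  counts <- count_codons(genes, per_gene = TRUE)
  enc_values <- enc(counts, partition)
  n <- length(genes)
  k <- ceiling(fraction * n)
  if (n >= 5) k <- max(k, 5L)
  k <- min(k, n)
  ord <- order(enc_values)          # stable: ties keep input order
  idx <- sort(ord[seq_len(k)])      # preserve input order within selection
  ref <- genes[idx]
  attr(ref, "enc") <- enc_values[idx]
  attr(ref, "reference_ids") <- gene_ids(genes)[idx]
  ref
}

#' Pooled RSCU of a reference gene set
#'
#' Computes [rscu()] on the codon counts pooled over all reference genes (the
#' codon-level usage profile the S_ij optimization is fitted against).
#'
#' @param reference A `genome_cds_set` (typically from [select_reference()]).
#' @param partition A [build_family_partition()]; defaults to the set's code.
#' @return Named RSCU vector over sense codons.
#' @export
reference_rscu <- function(reference, partition = NULL) {
  if (length(reference) == 0) stop("empty reference set")
  partition <- partition %||% build_family_partition(reference$genetic_code_id)
  rscu(count_codons(reference), partition)
}
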