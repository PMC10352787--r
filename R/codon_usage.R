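#' Partition sense codons into synonymous families
#'
#' Builds the synonymous-codon family structure of a translation table, with
#' stop codons excluded.  By default the six-fold families (Leu, Ser, Arg in
#' the standard code) are split into a two-fold and a four-fold block by
#' first-two-nucleotide identity, which is the family structure assumed by the
#' improved ENc (its correction has only K2/K3/K4 terms) and yields the
#' conventional maximum of 61 effective codons.
#'
#' @param genetic_code_id NCBI translation table identifier (default 1).
#' @param split_sixfold Split six-fold families into 2+4 blocks (default
#'   `TRUE`).
#' @return A `family_partition`: list of families (each with `aa`, `codons`,
#'   fold size `m`), the per-fold family counts `Ns`, `K2`, `K3`, `K4`, and a
#'   codon -> family index map.
#' @examples
#' p <- build_family_partition()
#' c(p$Ns, p$K2, p$K3, p$K4)
#' @export
build_family_partition <- function(genetic_code_id = 1, split_sixfold = TRUE) {
  code <- resolve_genetic_code(genetic_code_id)
  sense <- sense_codons(code)
  fam_codons <- split(sense, code[sense])
  families <- list()
  for (aa in names(fam_codons)) {
    codons <- fam_codons[[aa]]
    if (split_sixfold && length(codons) == 6) {
      blocks <- split(codons, substr(codons, 1, 2))
      for (b in names(blocks)) {
        families[[length(families) + 1L]] <-
          list(aa = aa, codons = blocks[[b]], m = length(blocks[[b]]))
      }
    } else {
      families[[length(families) + 1L]] <-
        list(aa = aa, codons = codons, m = length(codons))
    }
  }
  m_sizes <- vapply(families, `[[`, integer(1), "m")
  if (any(m_sizes > 4))
    stop("family of fold > 4 under genetic code ", genetic_code_id,
         "; use split_sixfold = TRUE")
  fam_of <- integer(length(sense))
  names(fam_of) <- sense
  for (i in seq_along(families)) fam_of[families[[i]]$codons] <- i
  structure(
    list(families = families, genetic_code_id = genetic_code_id,
         Ns = sum(m_sizes == 1), K2 = sum(m_sizes == 2),
         K3 = sum(m_sizes == 3), K4 = sum(m_sizes == 4),
         codon_family = fam_of, sense_codons = sense),
    class = "family_partition"
  )
}

#' @export
print.family_partition <- function(x, ...) {
  cat("family_partition (code ", x$genetic_code_id, "): ",
      length(x$families), " families; Ns=", x$Ns, " K2=", x$K2,
      " K3=", x$K3, " K4=", x$K4, "\n", sep = "")
  invisible(x)
}

#' Relative synonymous codon usage (RSCU)
#'
#' The ratio of each codon's observed count to the count expected if all
#' synonymous codons of its amino acid were used equally:
#' \eqn{RSCU_c = O_{ac} / (\frac{1}{k_a} \sum_{c' \in C_a} O_{ac'})}.
#' Values range from 0 to the family size \eqn{k_a}; each non-empty family's
#' RSCU values sum to exactly \eqn{k_a}.  Families with zero total counts are
#' undefined (`NA`) and listed in the `undefined_families` attribute.
#'
#' @param counts Named codon-count vector (pooled counts).
#' @param partition A [build_family_partition()] result.
#' @return Named numeric vector of RSCU values over sense codons.
#' @examples
#' p <- build_family_partition()
#' cc <- count_codons("TTTTTTTTTTTC")
#' rscu(cc, p)[c("TTT", "TTC")]
#' @export
rscu <- function(counts, partition) {
  x <- numeric(length(partition$sense_codons))
  names(x) <- partition$sense_codons
  present <- intersect(names(counts), names(x))
  x[present] <- counts[present]
  out <- rep(NA_real_, length(x))
  names(out) <- names(x)
  undefined <- character()
  for (fam in partition$families) {
    tot <- sum(x[fam$codons])
    if (tot == 0) {
      undefined <- c(undefined, fam$aa)
    } else {
      out[fam$codons] <- x[fam$codons] / (tot / fam$m)
    }
  }
  attr(out, "undefined_families") <- unique(undefined)
  attr(out, "meaning") <- "RSCU"
  out
}

#' Pseudocounted codon-family homozygosity F_CF
#'
#' The building block of the improved ENc:
#' \eqn{F_{CF} = \sum_{i=1}^{m} ((n_i + 1) / (n + m))^2} with
#' \eqn{n = \sum_i n_i}.  The +1 pseudocount keeps the statistic defined for
#' sparse families; F_CF lies in (0, 1], equals 1/m for an empty family and
#' approaches 1 under complete bias.
#'
#' @param family_counts Integer vector of codon counts within one synonymous
#'   family (length = family fold size m, at least 2).
#' @return The homozygosity value.
#' @examples
#' family_fcf(c(3, 1))
#' @export
family_fcf <- function(family_counts) {
  m <- length(family_counts)
  if (m < 2) stop("family fold size must be >= 2")
  n <- sum(family_counts)
  sum(((family_counts + 1) / (n + m))^2)
}

#' Improved effective number of codons (ENc)
#'
#' Gene- or genome-level codon usage bias on the scale (0, 61]:
#' \deqn{ENc = N_s + \sum_{m \in \{2,3,4\}} K_m
#'   \frac{\sum_j n_j}{\sum_j n_j F_{CF,j}}}
#' with sums over the families of fold \eqn{m} and the pseudocounted
#' homozygosity [family_fcf()].  Uniform synonymous usage drives ENc to
#' \eqn{N_s + 2K_2 + 3K_3 + 4K_4} (61 for the split standard code) and
#' complete bias to \eqn{N_s + K_2 + K_3 + K_4} (23).  A fold class with no
#' observed codons contributes its uniform-limit term \eqn{K_m m}, the
#' continuous limit of the pseudocounted form as counts vanish.
#'
#' @param counts Named codon-count vector, or a genes-by-codons count matrix
#'   for per-gene values.
#' @param partition A [build_family_partition()] result.
#' @return A single ENc value, or a vector (one per matrix row).  Rows with
#'   no multi-codon family counts yield `NA`; a single all-empty table errors.
#' @export
enc <- function(counts, partition) {
  cm <- as_count_matrix(counts)
  mat <- matrix(0, nrow(cm$mat), length(partition$sense_codons),
                dimnames = list(rownames(cm$mat), partition$sense_codons))
  present <- intersect(colnames(cm$mat), colnames(mat))
  mat[, present] <- cm$mat[, present]

  folds <- c(2L, 3L, 4L)
  sum_n <- matrix(0, nrow(mat), 3)
  sum_nf <- matrix(0, nrow(mat), 3)
  for (fam in partition$families) {
    if (fam$m < 2) next
    sub <- mat[, fam$codons, drop = FALSE]
    n <- rowSums(sub)
    fcf <- rowSums(((sub + 1) / (n + fam$m))^2)
    k <- match(fam$m, folds)
    sum_n[, k] <- sum_n[, k] + n
    sum_nf[, k] <- sum_nf[, k] + n * fcf
  }
  K <- c(partition$K2, partition$K3, partition$K4)
  terms <- matrix(0, nrow(mat), 3)
  for (k in 1:3) {
    if (K[k] == 0) next
    empty <- sum_n[, k] == 0
    terms[, k] <- ifelse(empty, K[k] * folds[k],
                         K[k] * sum_n[, k] / ifelse(empty, 1, sum_nf[, k]))
  }
  out <- partition$Ns + rowSums(terms)
  none <- rowSums(sum_n) == 0
  if (cm$single) {
    if (none) stop("all multi-codon families are empty")
    return(unname(out))
  }
  out[none] <- NA_real_
  stats::setNames(out, rownames(cm$mat))
}

#' CAI codon weights from a reference count table
#'
#' Sharp-Li relative adaptiveness: within each multi-codon family, each
#' codon's count divided by the family maximum.  Zero reference counts are
#' replaced by a 0.5 pseudocount before the ratio so rare codons keep a
#' finite penalty.  Single-codon families and stops are excluded.
#'
#' @param reference_counts Named codon-count vector of the reference gene set.
#' @param partition A [build_family_partition()] result.
#' @return Named weight vector over multi-codon-family sense codons; families
#'   with no reference counts are `NA`.
#' @export
cai_weights <- function(reference_counts, partition) {
  if (sum(reference_counts) == 0) stop("empty reference counts")
  x <- numeric(length(partition$sense_codons))
  names(x) <- partition$sense_codons
  present <- intersect(names(reference_counts), names(x))
  x[present] <- reference_counts[present]
  out <- c()
  for (fam in partition$families) {
    if (fam$m < 2) next
    cnt <- x[fam$codons]
    if (max(cnt) == 0) {
      w <- stats::setNames(rep(NA_real_, fam$m), fam$codons)
    } else {
      w <- pmax(cnt, 0.5) / max(cnt)
    }
    out <- c(out, w)
  }
  attr(out, "meaning") <- "CAI-weight"
  out
}

#' Codon adaptation index (CAI)
#'
#' Geometric mean of reference-derived codon weights over a gene's codon
#' occurrences (multi-codon families only), in (0, 1].
#'
#' @param gene_counts Named codon-count vector or genes-by-codons matrix.
#' @param weights Weights from [cai_weights()].
#' @return CAI value(s).
#' @export
cai <- function(gene_counts, weights) {
  scorable <- names(weights)[!is.na(weights)]
  cm <- as_count_matrix(gene_counts)
  use <- intersect(colnames(cm$mat), scorable)
  o <- cm$mat[, use, drop = FALSE]
  tot <- rowSums(o)
  if (cm$single && tot == 0) stop("gene has no scorable codons")
  val <- exp(as.vector(o %*% log(weights[use])) / tot)
  val[tot == 0] <- NA_real_
  if (cm$single) unname(val) else stats::setNames(val, rownames(cm$mat))
}

#' Synonymous codon usage orderliness (SCUO)
#'
#' Reference-free, entropy-based bias index in [0, 1].  For each family
#' \eqn{i} with observed counts, \eqn{H_i = -\sum_j p_{ij} \log_2 p_{ij}} and
#' the orderliness \eqn{O_i = (\log_2 m_i - H_i)/\log_2 m_i}; SCUO is the
#' count-share weighted mean of the \eqn{O_i} over families with
#' \eqn{m_i \ge 2}.  Uniform usage gives 0, single-codon usage gives 1.
#'
#' @param gene_counts Named codon-count vector or genes-by-codons matrix.
#' @param partition A [build_family_partition()] result.
#' @return SCUO value(s) in [0, 1].
#' @export
scuo <- function(gene_counts, partition) {
  cm <- as_count_matrix(gene_counts)
  mat <- matrix(0, nrow(cm$mat), length(partition$sense_codons),
                dimnames = list(rownames(cm$mat), partition$sense_codons))
  present <- intersect(colnames(cm$mat), colnames(mat))
  mat[, present] <- cm$mat[, present]
  num <- numeric(nrow(mat))
  den <- numeric(nrow(mat))
  for (fam in partition$families) {
    if (fam$m < 2) next
    sub <- mat[, fam$codons, drop = FALSE]
    n <- rowSums(sub)
    p <- sub / ifelse(n > 0, n, 1)
    plogp <- ifelse(p > 0, p * log2(p), 0)
    H <- -rowSums(plogp)
    O <- (log2(fam$m) - H) / log2(fam$m)
    num <- num + ifelse(n > 0, n * O, 0)
    den <- den + n
  }
  if (cm$single && den == 0) stop("no scorable families")
  val <- num / den
  val[den == 0] <- NA_real_
  if (cm$single) unname(val) else stats::setNames(val, rownames(cm$mat))
}

#' GC content of a gene set
#'
#' Per-gene (G+C)/(A+C+G+T) percentages, averaged arithmetically across genes
#' by default (each gene weighted equally); `pooled = TRUE` instead pools all
#' nucleotides before taking the ratio.
#'
#' @param genes A `genome_cds_set` (or [Biostrings::DNAStringSet]).
#' @param pooled Pool nucleotides across genes instead of averaging per-gene
#'   percentages (default `FALSE`).
#' @param per_gene Return the per-gene percentage vector instead of the mean.
#' @return GC percentage (0-100), or a per-gene vector.
#' @export
gc_content <- function(genes, pooled = FALSE, per_gene = FALSE) {
  seqs <- if (inherits(genes, "genome_cds_set")) genes$seqs else genes
  if (length(seqs) == 0) stop("empty gene set")
  counts <- Biostrings::letterFrequency(seqs, letters = DNA_BASES)
  gc <- counts[, "G"] + counts[, "C"]
  tot <- rowSums(counts)
  pct <- 100 * gc / tot
  if (per_gene) return(stats::setNames(pct, names(seqs)))
  if (pooled) 100 * sum(gc) / sum(tot) else mean(pct)
}
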