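# Wobble-pairing model, absolute/relative adaptiveness and gene tAI.

#' Codon-anticodon interaction classes
#'
#' `"WC"` is canonical Watson-Crick pairing at position 34; the wobble classes
#' are G:U (G34 reading NNU), I:C and I:A (inosine, genomically A34, reading
#' NNC/NNA), U:G (U34 reading NNG) and L:A (bacterial lysidine-CAT reading
#' AUA).
#'
#' @return Character vector of class labels.
#' @export
interaction_classes <- function() c("WC", "GU", "IC", "IA", "UG", "LA")

#' Build the wobble recognition rule set
#'
#' For every sense codon, lists the anticodons (DNA, 5'->3', wobble base
#' first) that can decode it and the interaction class of each pairing.
#' Third-position rules: codons ending U are read by the A34 anticodon (WC)
#' and its G34 variant (G:U); ending C by G34 (WC) and A34 (inosine, I:C);
#' ending A by U34 (WC) and A34 (inosine, I:A); ending G by C34 (WC) and U34
#' (U:G).  AUG and UGG are restricted to their Watson-Crick anticodons so
#' initiator-Met and Trp tRNAs are not credited with wobble decoding.  In
#' prokaryote mode AUA is additionally read by the lysidine-modified CAT
#' anticodon (L:A).
#'
#' @param genetic_code_id Translation table id (default 1).
#' @param prokaryote Add the lysidine L:A rule for AUA (default `FALSE`).
#' @return A `wobble_rules` data frame with columns `codon`, `anticodon`,
#'   `class`.
#' @export
wobble_rules <- function(genetic_code_id = 1, prokaryote = FALSE) {
  code <- resolve_genetic_code(genetic_code_id)
  sense <- sense_codons(code)
  rows <- vector("list", length(sense))
  sub34 <- function(ac, base) { substr(ac, 1, 1) <- base; ac }
  for (i in seq_along(sense)) {
    codon <- sense[i]
    wc <- revcomp3(codon)
    if (codon %in% c("ATG", "TGG")) {
      df <- data.frame(codon = codon, anticodon = wc, class = "WC")
    } else {
      third <- substr(codon, 3, 3)
      wob <- switch(third,
        T = data.frame(anticodon = sub34(wc, "G"), class = "GU"),
        C = data.frame(anticodon = sub34(wc, "A"), class = "IC"),
        A = data.frame(anticodon = sub34(wc, "A"), class = "IA"),
        G = data.frame(anticodon = sub34(wc, "T"), class = "UG"))
      df <- rbind(data.frame(anticodon = wc, class = "WC"), wob)
      df <- data.frame(codon = codon, df)
      if (prokaryote && codon == "ATA")
        df <- rbind(df, data.frame(codon = codon, anticodon = "CAT",
                                   class = "LA"))
    }
    rows[[i]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("wobble_rules", "data.frame"),
            genetic_code_id = genetic_code_id, prokaryote = prokaryote)
}

#' Anticodons recognizing a codon
#'
#' @param codon A sense codon (DNA).
#' @param rules A [wobble_rules()] table.
#' @return Data frame of (anticodon, class) pairs for the codon.
#' @examples
#' recognizers("GGC", wobble_rules())
#' @export
recognizers <- function(codon, rules) {
  codon <- toupper(chartr("U", "T", codon))
  hit <- as.data.frame(rules)[rules$codon == codon, c("anticodon", "class")]
  if (nrow(hit) == 0) {
    code <- resolve_genetic_code(attr(rules, "genetic_code_id"))
    if (codon %in% stop_codons(code)) stop("stop codon has no recognizers: ", codon)
    stop("unknown codon: ", codon)
  }
  rownames(hit) <- NULL
  hit
}

#' Construct an S_ij coupling-efficiency weight vector
#'
#' Values range from 0 (perfect codon-anticodon interaction) to 1 (weak
#' interaction).  Watson-Crick pairings are fixed at 0 by default; the wobble
#' classes are the free parameters the genetic algorithm infers.
#'
#' @param ... Named values among `GU`, `IC`, `IA`, `UG`, `LA`, `WC` (or a
#'   single named vector).
#' @return Named numeric vector over all interaction classes.
#' @examples
#' sij_weights(GU = 0.41, IC = 0.28)
#' @export
sij_weights <- function(...) {
  args <- list(...)
  if (length(args) == 1 && is.null(names(args)) && !is.null(names(args[[1]])))
    args <- as.list(args[[1]])
  s <- stats::setNames(numeric(length(interaction_classes())),
                       interaction_classes())
  if (length(args)) {
    vals <- unlist(args)
    bad <- setdiff(names(vals), interaction_classes())
    if (length(bad)) stop("unknown interaction class: ", paste(bad, collapse = ", "))
    s[names(vals)] <- vals
  }
  if (any(s < 0 | s > 1)) stop("S_ij values must lie in [0, 1]")
  s
}

#' Literature S_ij weights of the original tAI
#'
#' The fixed coupling efficiencies estimated for budding yeast in the
#' original tAI formulation (dos Reis et al. 2004), shipped as external
#' constants for the "otAI" comparator preset: s(G:U)=0.41, s(I:C)=0.28,
#' s(I:A)=0.9999, s(U:G)=0.68, s(L:A)=0.89.
#'
#' @return An [sij_weights()] vector.
#' @export
otai_sij <- function() {
  sij_weights(GU = 0.41, IC = 0.28, IA = 0.9999, UG = 0.68, LA = 0.89)
}

# Per-codon copy-number contributions by interaction class: a codons x
# classes matrix C with C[i, k] = total tGCN of class-k anticodons reading
# codon i, so W = C %*% (1 - s).  Precomputed once per (tgcn, rules) because
# the GA evaluates thousands of S vectors against the same pools.
adaptiveness_matrix <- function(tgcn, rules) {
  codons <- unique(rules$codon)
  classes <- interaction_classes()
  C <- matrix(0, length(codons), length(classes),
              dimnames = list(codons, classes))
  copies <- ifelse(rules$class == "LA", tgcn$lysidine_count,
                   tgcn$entries[rules$anticodon])
  copies[is.na(copies)] <- 0
  for (r in seq_len(nrow(rules))) {
    C[rules$codon[r], rules$class[r]] <-
      C[rules$codon[r], rules$class[r]] + copies[r]
  }
  C
}

#' Absolute adaptiveness W_i of each codon
#'
#' \deqn{W_i = \sum_{j=1}^{n_j} (1 - S_{ij})\, tGCN_{ij}} summed over the
#' anticodons that can recognize codon \eqn{i} under the wobble rules, where
#' \eqn{tGCN_{ij}} is the gene copy number of the j-th such anticodon.  The
#' lysidine L:A term draws its copy number from the table's
#' `lysidine_count`.
#'
#' @param tgcn A [tgcn_table()].
#' @param s An [sij_weights()] vector.
#' @param rules A [wobble_rules()] table.
#' @return An `adaptiveness_map` data frame with columns `codon`, `W` (and
#'   `w`, `substituted` once [relative_adaptiveness()] has been applied).
#' @examples
#' tg <- tgcn_table(c(ACC = 1, GCC = 2))
#' absolute_adaptiveness(tg, sij_weights(GU = 0.41), wobble_rules())["GGT", ]
#' @export
absolute_adaptiveness <- function(tgcn, s, rules) {
  C <- adaptiveness_matrix(tgcn, rules)
  s_full <- sij_weights(s)
  W <- as.vector(C %*% (1 - s_full))
  structure(
    data.frame(codon = rownames(C), W = W, w = NA_real_, substituted = FALSE,
               row.names = rownames(C)),
    class = c("adaptiveness_map", "data.frame")
  )
}

#' Relative adaptiveness w_i
#'
#' Normalizes each \eqn{W_i} to the maximum so that \eqn{w_i \in (0, 1]}.
#' Codons with \eqn{W_i = 0} (no recognizing tRNA copies) receive the
#' geometric mean of the non-zero \eqn{w} values, keeping the log in the tAI
#' geometric mean defined; such codons are flagged in `substituted`.
#'
#' @param map An `adaptiveness_map` from [absolute_adaptiveness()].
#' @return The map with `w` and `substituted` filled in.
#' @export
relative_adaptiveness <- function(map) {
  W <- map$W
  if (all(W == 0)) stop("all W values are zero")
  w <- W / max(W)
  zero <- w == 0
  if (any(zero)) w[zero] <- exp(mean(log(w[!zero])))
  map$w <- w
  map$substituted <- zero
  map
}

#' Gene-level tRNA adaptation index
#'
#' The geometric mean of the relative adaptiveness values over a gene's codon
#' occurrences: \eqn{tAI_g = \exp(\frac{1}{O_{tot}} \sum_i O_i \log w_i)},
#' stop codons excluded; lies in (0, 1].
#'
#' @param gene_counts Named codon-count vector or genes-by-codons matrix
#'   (from [count_codons()] with `per_gene = TRUE`).
#' @param map An `adaptiveness_map` with `w` filled in
#'   ([relative_adaptiveness()]).
#' @return tAI value(s).
#' @export
gene_tai <- function(gene_counts, map) {
  if (anyNA(map$w)) stop("relative adaptiveness not computed; call relative_adaptiveness()")
  cm <- as_count_matrix(gene_counts)
  use <- intersect(colnames(cm$mat), map$codon)
  o <- cm$mat[, use, drop = FALSE]
  tot <- rowSums(o)
  if (cm$single && tot == 0) stop("gene has no scorable codons")
  logw <- log(map[use, "w"])
  val <- exp(as.vector(o %*% logw) / tot)
  val[tot == 0] <- NA_real_
  if (cm$single) unname(val) else stats::setNames(val, rownames(cm$mat))
}

#' Write an adaptiveness map as TSV
#'
#' @param map An `adaptiveness_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_adaptiveness_tsv <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write S_ij weights as JSON
#'
#' @param s An [sij_weights()] vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sij_json <- function(s, path) {
  jsonlite::write_json(as.list(sij_weights(s)), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
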