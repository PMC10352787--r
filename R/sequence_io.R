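#' Read and validate coding sequences from a FASTA file
#'
#' Reads one CDS per FASTA record, applies validation filters and returns the
#' surviving genes together with a filter report.  Records are dropped (and
#' counted per reason) when their length is not a multiple of 3, they are
#' shorter than `min_codons`, their fraction of ambiguous (non-ACGT) bases
#' exceeds `max_ambiguous_frac`, or (in strict mode) they contain an internal
#' stop codon.
#'
#' @param path Path to a FASTA file (one coding sequence per record).
#' @param min_codons Minimum gene length in codons (default 30).
#' @param max_ambiguous_frac Maximum tolerated fraction of ambiguous bases
#'   (default 0.05).
#' @param strict Drop genes with internal stop codons (default `TRUE`).
#' @param genetic_code NCBI translation table identifier (default 1).
#' @return A `genome_cds_set`: the validated genes (as a named
#'   [Biostrings::DNAStringSet]), the genetic code id and a `filter_report`
#'   listing input/kept/dropped counts per reason.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">g1", strrep("ATGGCT", 20), ">g2", "ATGGCTTAA"), fa)
#' cds <- read_cds_fasta(fa)
#' cds$filter_report
#' @export
read_cds_fasta <- function(path, min_codons = 30, max_ambiguous_frac = 0.05,
                           strict = TRUE, genetic_code = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) stop("duplicate record ids in ", path)
  names(seqs) <- ids
  genome_cds_set(seqs, genetic_code_id = genetic_code, min_codons = min_codons,
                 max_ambiguous_frac = max_ambiguous_frac, strict = strict)
}

#' Construct a validated CDS set from sequences already in memory
#'
#' Applies the same filters as [read_cds_fasta()] to a named
#' [Biostrings::DNAStringSet] (or named character vector of DNA strings).
#'
#' @inheritParams read_cds_fasta
#' @param seqs Named [Biostrings::DNAStringSet] or character vector.
#' @return A `genome_cds_set` object.
#' @export
genome_cds_set <- function(seqs, genetic_code_id = 1, min_codons = 30,
                           max_ambiguous_frac = 0.05, strict = TRUE) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  code <- resolve_genetic_code(genetic_code_id)
  n_in <- length(seqs)
  w <- Biostrings::width(seqs)

  drop_len <- (w %% 3L) != 0L
  drop_short <- !drop_len & (w %/% 3L) < min_codons
  ok <- !(drop_len | drop_short)

  amb <- rep(0, n_in)
  if (any(ok)) {
    acgt <- rowSums(Biostrings::letterFrequency(seqs[ok], letters = DNA_BASES))
    amb[ok] <- (w[ok] - acgt) / w[ok]
  }
  drop_amb <- ok & amb > max_ambiguous_frac
  ok <- ok & !drop_amb

  drop_stop <- rep(FALSE, n_in)
  if (strict && any(ok)) {
    body <- Biostrings::subseq(seqs[ok], 1L, pmax(w[ok] - 3L, 3L))
    aa <- suppressWarnings(
      Biostrings::translate(body, genetic.code = Biostrings::getGeneticCode(
        as.character(genetic_code_id)), if.fuzzy.codon = "X")
    )
    drop_stop[ok] <- Biostrings::vcountPattern("*", aa) > 0
    ok <- ok & !drop_stop
  }

  report <- list(
    input = n_in,
    kept = sum(ok),
    length_not_multiple_of_3 = sum(drop_len),
    too_short = sum(drop_short),
    too_ambiguous = sum(drop_amb),
    internal_stop = sum(drop_stop)
  )
  if (report$kept == 0) stop("no genes survived CDS validation filters")

  structure(
    list(seqs = seqs[ok], genetic_code_id = genetic_code_id,
         filter_report = report),
    class = "genome_cds_set"
  )
}

#' @export
length.genome_cds_set <- function(x) length(x$seqs)

#' @export
`[.genome_cds_set` <- function(x, i) {
  x$seqs <- x$seqs[i]
  x
}

#' @export
print.genome_cds_set <- function(x, ...) {
  cat("genome_cds_set:", length(x$seqs), "genes, genetic code",
      x$genetic_code_id, "\n")
  invisible(x)
}

#' Gene identifiers of a CDS set
#' @param x A `genome_cds_set`.
#' @return Character vector of gene ids in input order.
#' @export
gene_ids <- function(x) names(x$seqs)

#' Count codons in genes
#'
#' Tallies codon occurrences in reading frame (step 3).  Codons containing
#' ambiguous bases are skipped and reported via the `skipped` attribute.
#'
#' @param x A `genome_cds_set`, [Biostrings::DNAStringSet], or a single DNA
#'   string.
#' @param drop_stops Drop stop-codon columns (default `TRUE`).
#' @param per_gene Return a genes-by-codons matrix instead of pooled counts.
#' @param genetic_code Translation table id (taken from `x` when available).
#' @return Named codon-count vector, or a count matrix when `per_gene = TRUE`;
#'   attribute `skipped` holds the number of ambiguous codons not tallied.
#' @examples
#' count_codons("ATGGCTGCT")
#' @export
count_codons <- function(x, drop_stops = TRUE, per_gene = FALSE,
                         genetic_code = NULL) {
  if (inherits(x, "genome_cds_set")) {
    genetic_code <- genetic_code %||% x$genetic_code_id
    seqs <- x$seqs
  } else if (is.character(x)) {
    seqs <- Biostrings::DNAStringSet(x)
  } else {
    seqs <- x
  }
  genetic_code <- genetic_code %||% 1
  if (any(Biostrings::width(seqs) %% 3L != 0L))
    stop("sequence length not a multiple of 3")
  m <- Biostrings::trinucleotideFrequency(seqs, step = 3)
  rownames(m) <- names(seqs)
  skipped <- sum(Biostrings::width(seqs) %/% 3L) - sum(m)
  if (drop_stops) {
    code <- resolve_genetic_code(genetic_code)
    m <- m[, sense_codons(code), drop = FALSE]
  }
  out <- if (per_gene) m else colSums(m)
  attr(out, "skipped") <- skipped
  attr(out, "genetic_code_id") <- genetic_code
  out
}

#' Construct a tRNA gene copy number table
#'
#' @param entries Named non-negative vector: anticodon (DNA, 5'->3', wobble
#'   base 34 first) -> gene copy number.
#' @param lysidine_count Copy number of bacterial tRNA-Ile2 (CAT anticodon,
#'   lysidine-modified, decodes ATA); default 0.
#' @return A `tgcn_table` object.
#' @export
tgcn_table <- function(entries, lysidine_count = 0) {
  if (is.null(names(entries)) || any(!nzchar(names(entries))))
    stop("entries must be named by anticodon")
  nm <- toupper(chartr("U", "T", names(entries)))
  if (!all(is_valid_trinucleotide(nm)))
    stop("malformed anticodon(s): ",
         paste(names(entries)[!is_valid_trinucleotide(nm)], collapse = ", "))
  if (any(entries < 0)) stop("negative tRNA gene copy number")
  if (lysidine_count < 0) stop("negative lysidine count")
  ent <- tapply(as.numeric(entries), nm, sum)
  ent <- ent[order(names(ent))]
  if (all(ent == 0) && lysidine_count == 0)
    stop("all tRNA gene copy numbers are zero")
  structure(list(entries = c(ent), lysidine_count = as.numeric(lysidine_count)),
            class = "tgcn_table")
}

#' @export
print.tgcn_table <- function(x, ...) {
  cat("tgcn_table:", length(x$entries), "anticodons, total copies",
      sum(x$entries), "\n")
  if (x$lysidine_count > 0)
    cat("  lysidine-modified Ile2(CAT) copies:", x$lysidine_count, "\n")
  invisible(x)
}

#' Read a tRNA gene copy number table
#'
#' Parses a GtRNAdb-style delimited export with columns
#' `anticodon,count[,isotype]` (TSV or CSV, header auto-detected).  Duplicate
#' anticodon rows are summed.  Rows whose isotype marks bacterial Ile2 with a
#' CAT anticodon populate the lysidine count instead of the Met CAT entry.
#'
#' @param path Path to the delimited file.
#' @param lysidine_count Override used when no isotype column is present
#'   (default 0).
#' @return A [tgcn_table()].
#' @export
read_tgcn <- function(path, lysidine_count = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  probe <- utils::read.table(path, sep = sep, header = FALSE,
                             stringsAsFactors = FALSE, nrows = 1)
  has_header <- is.na(suppressWarnings(as.numeric(probe[[2]])))
  df <- utils::read.table(path, sep = sep, header = has_header,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expected columns anticodon,count[,isotype]")
  anticodon <- toupper(chartr("U", "T", as.character(df[[1]])))
  count <- suppressWarnings(as.numeric(df[[2]]))
  if (anyNA(count)) stop("non-numeric copy number in ", path)
  if (any(count < 0)) stop("negative copy number in ", path)
  if (!all(is_valid_trinucleotide(anticodon)))
    stop("malformed anticodon(s) in ", path)
  isotype <- if (ncol(df) >= 3) as.character(df[[3]]) else NULL

  lys <- 0
  if (!is.null(isotype)) {
    is_ile2 <- grepl("^ile2$", trimws(isotype), ignore.case = TRUE) &
      anticodon == "CAT"
    lys <- sum(count[is_ile2])
    anticodon <- anticodon[!is_ile2]
    count <- count[!is_ile2]
  } else if (!is.null(lysidine_count)) {
    lys <- lysidine_count
  }
  tgcn_table(stats::setNames(count, anticodon), lysidine_count = lys)
}

#' Write a tRNA gene copy number table
#'
#' @param tgcn A [tgcn_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_tgcn <- function(tgcn, path) {
  df <- data.frame(anticodon = names(tgcn$entries), count = tgcn$entries,
                   isotype = "", row.names = NULL)
  if (tgcn$lysidine_count > 0)
    df <- rbind(df, data.frame(anticodon = "CAT", count = tgcn$lysidine_count,
                               isotype = "Ile2"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-gene scores as a delimited table
#'
#' @param scores Named numeric vector (gene id -> score) or a data frame whose
#'   first two columns are gene id and score.  Row order is preserved.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gene_scores <- function(scores, path) {
  if (is.data.frame(scores)) {
    df <- data.frame(gene_id = scores[[1]], score = scores[[2]])
  } else {
    if (length(scores) == 0) stop("empty score map")
    if (is.null(names(scores))) stop("scores must be named by gene id")
    df <- data.frame(gene_id = names(scores), score = as.numeric(scores))
  }
  if (nrow(df) == 0) stop("empty score map")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-gene score table written by [write_gene_scores()]
#'
#' @param path TSV path with columns `gene_id`, `score`.
#' @return Named numeric vector in file order.
#' @export
read_gene_scores <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}
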