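# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# All 64 codons in the lexicographic (AAA..TTT) order used by
# Biostrings::trinucleotideFrequency, so count matrices line up by name.
all_codons <- function() {
  g <- expand.grid(b3 = DNA_BASES, b2 = DNA_BASES, b1 = DNA_BASES,
                   stringsAsFactors = FALSE)
  sort(paste0(g$b1, g$b2, g$b3))
}

# Reverse complement of codon/anticodon trinucleotides (vectorised).
revcomp3 <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  paste0(substr(comp, 3, 3), substr(comp, 2, 2), substr(comp, 1, 1))
}

is_valid_trinucleotide <- function(x) {
  grepl("^[ACGT]{3}$", x)
}

# Resolve an NCBI translation table id to a codon -> amino-acid map.
# Stops are "*"; unknown ids error.
resolve_genetic_code <- function(genetic_code_id) {
  id <- as.character(genetic_code_id)
  code <- tryCatch(
    Biostrings::getGeneticCode(id),
    error = function(e) stop("unknown genetic code id: ", id, call. = FALSE)
  )
  code[all_codons()]
}

sense_codons <- function(code) names(code)[code != "*"]

stop_codons <- function(code) names(code)[code == "*"]

`%||%` <- function(a, b) if (is.null(a)) b else a

# Coerce per-gene count input (named vector or genes x codons matrix) to a
# matrix with codon column names; returns list(mat, single) where single
# marks that the caller passed one count table.
as_count_matrix <- function(counts) {
  if (is.matrix(counts)) {
    if (is.null(colnames(counts))) stop("count matrix must have codon column names")
    list(mat = counts, single = FALSE)
  } else {
    if (is.null(names(counts))) stop("counts must be named by codon")
    list(mat = matrix(counts, nrow = 1, dimnames = list(NULL, names(counts))),
         single = TRUE)
  }
}
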