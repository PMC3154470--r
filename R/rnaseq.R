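#' @keywords internal
"_PACKAGE"

RNA_BASES <- c("A", "C", "G", "U")

# Watson-Crick complement on the RNA alphabet; G:U wobble is NOT a pair here.
RNA_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")

#' Normalize a nucleotide sequence to the RNA alphabet
#'
#' Uppercases the input, maps T to U (so DNA input is accepted), and rejects
#' any character outside \{A, C, G, U\}. All sequence-facing functions in the
#' package call this, so downstream code can assume a clean RNA string.
#'
#' @param x character vector of sequences (DNA or RNA alphabet).
#' @param what label used in error messages.
#' @return character vector of uppercase RNA sequences.
#' @examples
#' as_rna("acgt")  # "ACGU"
#' @export
as_rna <- function(x, what = "sequence") {
  if (!is.character(x)) stop(what, " must be a character vector", call. = FALSE)
  out <- chartr("tT", "uU", x)
  out <- toupper(out)
  bad <- grepl("[^ACGU]", out)
  if (any(bad)) {
    offender <- gsub("[ACGU]", "", out[bad][1])
    stop(what, " contains invalid characters ('",
         substr(offender, 1, 5), "'); expected A/C/G/U (T accepted)",
         call. = FALSE)
  }
  out
}

#' Split a sequence into single bases
#' @param seq one RNA string (already normalized).
#' @return character vector of bases.
#' @keywords internal
seq_bases <- function(seq) {
  strsplit(seq, "", fixed = TRUE)[[1]]
}

#' Reverse complement on the RNA alphabet
#'
#' The antisense (guide) strand of an siRNA against a sense-strand target
#' window is the RNA reverse complement of that window.
#'
#' @param x character vector of RNA/DNA sequences.
#' @return character vector of reverse-complemented RNA sequences.
#' @examples
#' rna_revcomp("UCUGAUGUACUUUCCACUG")  # "CAGUGGAAAGUACAUCAGA"
#' @export
rna_revcomp <- function(x) {
  x <- as_rna(x)
  vapply(x, function(s) {
    b <- rev(seq_bases(s))
    paste(RNA_COMPLEMENT[b], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Validate an siRNA antisense sequence
#'
#' @param x character vector.
#' @param lengths allowed lengths (default 19 or 21 nt).
#' @return normalized RNA sequences.
#' @export
as_sirna <- function(x, lengths = c(19L, 21L)) {
  x <- as_rna(x, what = "siRNA antisense")
  n <- nchar(x)
  if (any(!n %in% lengths)) {
    stop("siRNA antisense must be ", paste(lengths, collapse = " or "),
         " nt long, got length ", paste(unique(n[!n %in% lengths]), collapse = ", "),
         call. = FALSE)
  }
  x
}

# enumerate all k-mers over ACGU in lexicographic order (A < C < G < U,
# leftmost position most significant)
all_kmers <- function(k) {
  if (k == 1L) return(RNA_BASES)
  eg <- expand.grid(rep(list(RNA_BASES), k),
                    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  do.call(paste0, eg[, rev(seq_len(k)), drop = FALSE])
}
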