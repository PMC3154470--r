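# Nucleotide feature encoders
#
# Every encoder maps one RNA sequence to a fixed-length named numeric vector.
# Composition encoders return fractions summing to 1; positional encoders
# return one-hot blocks ordered 5'->3'. Positions are 1-based on the
# antisense strand throughout.

#' k-mer (mono/di/tri/tetra-nucleotide) composition
#'
#' Fraction of each overlapping k-mer among the \code{L - k + 1} windows of
#' the sequence, reported in lexicographic A < C < G < U order. Dimensions
#' are 4, 16, 64 and 256 for k = 1..4.
#'
#' @param seq one RNA sequence.
#' @param k word size, 1 to 4.
#' @return named numeric vector of length \code{4^k} summing to 1.
#' @examples
#' kmer_composition("ACGU", 1)
#' kmer_composition("AAAC", 2)[c("AA", "AC")]  # 2/3, 1/3
#' @export
kmer_composition <- function(seq, k) {
  seq <- as_rna(seq)
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > 4L) {
    stop("k must be an integer in 1..4", call. = FALSE)
  }
  L <- nchar(seq)
  if (L < k) stop("sequence shorter than k", call. = FALSE)
  starts <- seq_len(L - k + 1L)
  words <- substring(seq, starts, starts + k - 1L)
  lev <- all_kmers(k)
  counts <- table(factor(words, levels = lev))
  out <- as.numeric(counts) / length(words)
  names(out) <- lev
  out
}

#' Split nucleotide composition
#'
#' The sequence is divided into two (nearly) equal halves and the k-mer
#' composition of each half is computed separately and concatenated,
#' doubling the dimension. For odd lengths the middle base is shared by
#' both halves (a 21-mer splits into the first 11 nt and the last 11 nt),
#' which reproduces the standard dimensions 8/32/128 for k = 1..3 on
#' 21-nt siRNAs.
#'
#' @inheritParams kmer_composition
#' @return named numeric vector of length \code{2 * 4^k}.
#' @export
split_composition <- function(seq, k) {
  seq <- as_rna(seq)
  L <- nchar(seq)
  half <- ceiling(L / 2)
  if (half < k) stop("sequence too short to split for k = ", k, call. = FALSE)
  h1 <- substr(seq, 1L, half)
  h2 <- substr(seq, L - half + 1L, L)
  v1 <- kmer_composition(h1, k)
  v2 <- kmer_composition(h2, k)
  names(v1) <- paste0("h1.", names(v1))
  names(v2) <- paste0("h2.", names(v2))
  c(v1, v2)
}

#' Higher-order (gapped) nucleotide composition
#'
#' Generalizes k-mer composition to non-adjacent bases: an order-\code{o}
#' n-tuple reads the bases at positions \code{(i, i + o, ..., i + (n-1) o)}.
#' Order 1 recovers the contiguous composition; second-order dinucleotides
#' pair the i-th base with the (i+2)-th, capturing single-gap interactions.
#'
#' @param seq one RNA sequence.
#' @param n tuple size (2..4).
#' @param order positional step between tuple members (>= 2).
#' @return named numeric vector of length \code{4^n} summing to 1.
#' @examples
#' gapped_composition("ACGU", n = 2, order = 2)[c("AG", "CU")]  # 0.5, 0.5
#' @export
gapped_composition <- function(seq, n, order) {
  seq <- as_rna(seq)
  n <- as.integer(n); order <- as.integer(order)
  if (length(n) != 1L || !n %in% 2:4) stop("n must be 2, 3 or 4", call. = FALSE)
  if (length(order) != 1L || is.na(order) || order < 2L) {
    stop("order must be an integer >= 2", call. = FALSE)
  }
  L <- nchar(seq)
  span <- (n - 1L) * order
  if (span >= L) stop("tuple span exceeds sequence length", call. = FALSE)
  b <- seq_bases(seq)
  starts <- seq_len(L - span)
  words <- vapply(starts, function(i) {
    paste(b[i + (0:(n - 1L)) * order], collapse = "")
  }, character(1))
  lev <- all_kmers(n)
  counts <- table(factor(words, levels = lev))
  out <- as.numeric(counts) / length(words)
  names(out) <- lev
  out
}

# one-hot encode a vector of bases as a 4 x length(b) set of indicator blocks
onehot_base <- function(b) {
  m <- outer(RNA_BASES, b, "==") * 1
  rownames(m) <- RNA_BASES
  m
}

#' Positional one-hot (binary pattern) encoding
#'
#' Each position contributes a 4-bit indicator block (A = 1000, C = 0100,
#' G = 0010, U = 0001), 5'->3'. Dimension is 4L (84 for a 21-mer, 76 for a
#' 19-mer).
#'
#' @param seq one RNA sequence.
#' @return named numeric 0/1 vector of length \code{4 * nchar(seq)}.
#' @export
binary_pattern <- function(seq) {
  seq <- as_rna(seq)
  b <- seq_bases(seq)
  m <- onehot_base(b)
  out <- as.numeric(m)
  names(out) <- paste0("pos", sprintf("%02d", rep(seq_along(b), each = 4)),
                       ".", rep(RNA_BASES, length(b)))
  out
}

#' Positional one-hot dinucleotide encoding
#'
#' One 16-bit indicator block over the dinucleotide alphabet for each of the
#' \code{L - 1} consecutive positions. Dimension 320 for a 21-mer.
#'
#' @param seq one RNA sequence (length >= 2).
#' @return named numeric 0/1 vector of length \code{16 * (nchar(seq) - 1)}.
#' @export
binary_dinucleotide <- function(seq) {
  seq <- as_rna(seq)
  L <- nchar(seq)
  if (L < 2L) stop("sequence must have length >= 2", call. = FALSE)
  din <- substring(seq, 1:(L - 1L), 2:L)
  lev <- all_kmers(2L)
  m <- outer(lev, din, "==") * 1
  out <- as.numeric(m)
  names(out) <- paste0("pos", sprintf("%02d", rep(seq_len(L - 1L), each = 16)),
                       ".", rep(lev, L - 1L))
  out
}

#' Condensed (hairpin-folded) one-hot encoding
#'
#' The sequence is folded onto itself so the 5' and 3' ends coincide, and
#' the one-hot blocks of mirrored positions j and L+1-j are summed
#' elementwise. The middle base of an odd-length sequence is dropped.
#' Dimension is \code{4 * floor(L / 2)} (40 for a 21-mer).
#'
#' @param seq one RNA sequence.
#' @return named numeric vector with entries in \{0, 1, 2\}.
#' @export
condensed_binary <- function(seq) {
  seq <- as_rna(seq)
  L <- nchar(seq)
  half <- L %/% 2L
  if (half < 1L) stop("sequence must have length >= 2", call. = FALSE)
  b <- seq_bases(seq)
  m <- onehot_base(b[seq_len(half)]) + onehot_base(b[L + 1L - seq_len(half)])
  out <- as.numeric(m)
  names(out) <- paste0("fold", sprintf("%02d", rep(seq_len(half), each = 4)),
                       ".", rep(RNA_BASES, half))
  out
}

#' Positional AU/GC class encoding
#'
#' Two bits per position: \code{[1, 0]} for A or U (weak pair), \code{[0, 1]}
#' for G or C (strong pair). Dimension 2L (42 for a 21-mer).
#'
#' @param seq one RNA sequence.
#' @return named numeric 0/1 vector of length \code{2 * nchar(seq)}.
#' @export
au_gc_pattern <- function(seq) {
  seq <- as_rna(seq)
  b <- seq_bases(seq)
  au <- as.numeric(b %in% c("A", "U"))
  out <- as.numeric(rbind(au, 1 - au))
  names(out) <- paste0("pos", sprintf("%02d", rep(seq_along(b), each = 2)),
                       ".", rep(c("AU", "GC"), length(b)))
  out
}

#' Per-position hydrogen-bond count
#'
#' 3 for G or C (three hydrogen bonds), 2 for A or U. Dimension L.
#'
#' @param seq one RNA sequence.
#' @return named numeric vector with entries in \{2, 3\}.
#' @examples
#' hydrogen_bond("GCAU")  # 3 3 2 2
#' @export
hydrogen_bond <- function(seq) {
  seq <- as_rna(seq)
  b <- seq_bases(seq)
  out <- ifelse(b %in% c("G", "C"), 3, 2)
  names(out) <- paste0("pos", sprintf("%02d", seq_along(b)))
  out
}

#' Positional thermodynamic (nearest-neighbor stacking) profile
#'
#' Looks up the nearest-neighbor free energy of the dinucleotide starting at
#' each of positions 1..19, yielding a 19-dimensional profile for a 21-nt
#' siRNA. The energy table is configuration: the package ships a standard
#' RNA Watson-Crick nearest-neighbor delta-G(37 C) set
#' (\code{default_nn_table()}), and any complete 16-entry table can be
#' supplied instead.
#'
#' @param seq one RNA sequence of length >= 20.
#' @param nn_table named numeric vector mapping all 16 dinucleotides to an
#'   energy (kcal/mol).
#' @return named numeric vector of length 19.
#' @export
thermo_profile <- function(seq, nn_table = default_nn_table()) {
  seq <- as_rna(seq)
  L <- nchar(seq)
  if (L < 20L) stop("thermo_profile requires length >= 20", call. = FALSE)
  lev <- all_kmers(2L)
  missing <- setdiff(lev, names(nn_table))
  if (length(missing)) {
    stop("nearest-neighbor table missing dinucleotide(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  din <- substring(seq, 1:19, 2:20)
  out <- as.numeric(nn_table[din])
  names(out) <- paste0("step", sprintf("%02d", 1:19))
  out
}

#' Standard RNA nearest-neighbor free-energy table
#'
#' Watson-Crick nearest-neighbor stacking free energies at 37 C (kcal/mol),
#' read from the TSV shipped with the package. Used as the default energy
#' table for \code{\link{thermo_profile}}.
#'
#' @param path TSV file with columns \code{dinucleotide} and \code{energy};
#'   defaults to the packaged table.
#' @return named numeric vector of length 16.
#' @export
default_nn_table <- function(path = system.file("extdata", "nn_dg37.tsv",
                                                package = "sirnadesign")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("nearest-neighbor table file not found", call. = FALSE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("dinucleotide", "energy") %in% names(tab))) {
    stop("nearest-neighbor TSV must have columns 'dinucleotide' and 'energy'",
         call. = FALSE)
  }
  stats::setNames(tab$energy, as_rna(tab$dinucleotide))
}
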