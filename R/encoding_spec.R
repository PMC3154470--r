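# Encoder registry and hybrid feature assembly
#
# An encoding_spec is an ordered list of encoder names drawn from a fixed
# registry, plus the target scaling range. Hybrid vectors are the
# concatenation of the component encoders in spec order, with stable,
# encoder-prefixed column labels.

ENCODER_REGISTRY <- c("mono", "di", "tri", "tetra",
                      "split_mono", "split_di", "split_tri",
                      "gapped_di_k", "gapped_tri_k",
                      "binary", "binary_di", "condensed", "au_gc",
                      "hbond", "thermo", "accessibility")

# parse an encoder name into (family, k/order); gapped encoders carry their
# order as a numeric suffix, e.g. "gapped_di_2"
parse_encoder <- function(name) {
  if (name %in% c("mono", "di", "tri", "tetra")) {
    return(list(family = "kmer",
                k = match(name, c("mono", "di", "tri", "tetra"))))
  }
  if (name %in% c("split_mono", "split_di", "split_tri")) {
    return(list(family = "split",
                k = match(name, c("split_mono", "split_di", "split_tri"))))
  }
  m <- regmatches(name, regexec("^gapped_(di|tri)_([0-9]+)$", name))[[1]]
  if (length(m) == 3L) {
    return(list(family = "gapped",
                n = if (m[2] == "di") 2L else 3L,
                order = as.integer(m[3])))
  }
  if (name %in% c("binary", "binary_di", "condensed", "au_gc",
                  "hbond", "thermo", "accessibility")) {
    return(list(family = name))
  }
  stop("unknown encoder '", name, "'; registry: ",
       paste(ENCODER_REGISTRY, collapse = ", "), call. = FALSE)
}

#' Define an ordered encoder configuration
#'
#' @param encoders character vector of registry names, applied in order.
#'   Available: \code{mono, di, tri, tetra} (k-mer composition),
#'   \code{split_mono, split_di, split_tri} (two-half composition),
#'   \code{gapped_di_<o>, gapped_tri_<o>} (order-o gapped composition, e.g.
#'   \code{"gapped_tri_2"}), \code{binary} (positional one-hot),
#'   \code{binary_di}, \code{condensed}, \code{au_gc}, \code{hbond},
#'   \code{thermo}, \code{accessibility} (one scalar appended per sequence).
#' @param scale_low,scale_high target range for min-max feature scaling
#'   (defaults 1 and 10).
#' @param nn_table nearest-neighbor energy table, used only by the
#'   \code{thermo} encoder.
#' @return an object of class \code{encoding_spec}.
#' @examples
#' spec21 <- encoding_spec()  # mono+di+tri+binary: 168 dims on a 21-mer
#' @export
encoding_spec <- function(encoders = c("mono", "di", "tri", "binary"),
                          scale_low = 1, scale_high = 10,
                          nn_table = NULL) {
  stopifnot(is.character(encoders), length(encoders) >= 1L)
  for (e in encoders) parse_encoder(e)  # validate against registry
  if (!is.numeric(scale_low) || !is.numeric(scale_high) ||
      scale_high <= scale_low) {
    stop("scale_high must exceed scale_low", call. = FALSE)
  }
  if ("thermo" %in% encoders && is.null(nn_table)) {
    nn_table <- default_nn_table()
  }
  structure(list(encoders = encoders,
                 scale_low = scale_low, scale_high = scale_high,
                 nn_table = nn_table),
            class = "encoding_spec")
}

#' @export
print.encoding_spec <- function(x, ...) {
  cat("encoding_spec:", paste(x$encoders, collapse = " + "),
      sprintf("| scaling to [%g, %g]\n", x$scale_low, x$scale_high))
  invisible(x)
}

# run a single registry encoder on one sequence
run_encoder <- function(name, seq, spec, accessibility = NULL) {
  p <- parse_encoder(name)
  v <- switch(p$family,
    kmer   = kmer_composition(seq, p$k),
    split  = split_composition(seq, p$k),
    gapped = gapped_composition(seq, n = p$n, order = p$order),
    binary = binary_pattern(seq),
    binary_di = binary_dinucleotide(seq),
    condensed = condensed_binary(seq),
    au_gc  = au_gc_pattern(seq),
    hbond  = hydrogen_bond(seq),
    thermo = thermo_profile(seq, spec$nn_table),
    accessibility = {
      if (is.null(accessibility) || is.na(accessibility)) {
        stop("encoding spec includes 'accessibility' but no accessibility ",
             "value was supplied", call. = FALSE)
      }
      stats::setNames(as.numeric(accessibility), "value")
    },
    stop("unhandled encoder family", call. = FALSE)
  )
  stats::setNames(v, paste0(name, ".", names(v)))
}

#' Build one hybrid feature vector
#'
#' Concatenates the spec's component encoders, in order, on a single
#' sequence. The default mono+di+tri+binary spec yields 168 features on a
#' 21-nt siRNA and 160 on a 19-nt siRNA.
#'
#' @param seq one RNA sequence.
#' @param spec an \code{\link{encoding_spec}}.
#' @param accessibility optional scalar, consumed by the
#'   \code{accessibility} encoder if present in the spec.
#' @return named numeric vector (unscaled).
#' @export
build_hybrid <- function(seq, spec = encoding_spec(), accessibility = NULL) {
  seq <- as_rna(seq)
  parts <- lapply(spec$encoders, function(e) {
    tryCatch(run_encoder(e, seq, spec, accessibility),
             error = function(cnd) {
               stop("encoder '", e, "': ", conditionMessage(cnd), call. = FALSE)
             })
  })
  do.call(c, parts)
}

#' Encode a set of sequences into a feature matrix
#'
#' @param seqs character vector of equal-length RNA sequences.
#' @param spec an \code{\link{encoding_spec}}.
#' @param accessibility optional numeric vector, one value per sequence.
#' @param ids row identifiers (default: names of \code{seqs} or indices).
#' @return numeric matrix, rows = sequences, columns = labelled features.
#' @export
encode_features <- function(seqs, spec = encoding_spec(),
                            accessibility = NULL, ids = NULL) {
  seqs <- as_rna(seqs)
  if (length(seqs) == 0L) stop("no sequences to encode", call. = FALSE)
  if (length(unique(nchar(seqs))) != 1L) {
    stop("all sequences must have the same length", call. = FALSE)
  }
  if (!is.null(accessibility) && length(accessibility) != length(seqs)) {
    stop("accessibility must have one value per sequence", call. = FALSE)
  }
  rows <- lapply(seq_along(seqs), function(i) {
    build_hybrid(seqs[i], spec,
                 accessibility = if (is.null(accessibility)) NULL
                                 else accessibility[i])
  })
  m <- do.call(rbind, rows)
  rownames(m) <- if (!is.null(ids)) ids
                 else if (!is.null(names(seqs))) names(seqs)
                 else as.character(seq_along(seqs))
  m
}

#' Fit a min-max feature scaler on training rows
#'
#' Linear map of each column from its training min/max onto
#' \code{[low, high]}; constant columns map to \code{low}. Applying the
#' fitted scaler to held-out rows uses the training min/max without
#' clipping, so out-of-range test values extrapolate linearly.
#'
#' @param train numeric feature matrix (training rows only).
#' @param low,high target range (defaults 1 and 10).
#' @return object of class \code{scaler_params}.
#' @export
fit_scaler <- function(train, low = 1, high = 10) {
  if (!is.matrix(train) || nrow(train) == 0L) {
    stop("training matrix must be non-empty", call. = FALSE)
  }
  structure(list(min = apply(train, 2, min),
                 max = apply(train, 2, max),
                 low = low, high = high,
                 columns = colnames(train)),
            class = "scaler_params")
}

#' Apply a fitted scaler to a feature matrix
#'
#' @param m numeric matrix with the same columns as the training matrix.
#' @param params a \code{scaler_params} object from \code{\link{fit_scaler}}.
#' @return scaled matrix of the same shape.
#' @export
apply_scaler <- function(m, params) {
  stopifnot(inherits(params, "scaler_params"))
  if (!is.matrix(m)) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(m)))
  if (!is.null(params$columns) && !is.null(colnames(m)) &&
      !identical(colnames(m), params$columns)) {
    stop("feature columns do not match the fitted scaler", call. = FALSE)
  }
  rng <- params$max - params$min
  scale_col <- function(j) {
    if (rng[j] == 0) rep(params$low, nrow(m))
    else params$low + (params$high - params$low) * (m[, j] - params$min[j]) / rng[j]
  }
  out <- vapply(seq_len(ncol(m)), scale_col, numeric(nrow(m)))
  if (nrow(m) == 1L) out <- matrix(out, nrow = 1)
  dimnames(out) <- dimnames(m)
  out
}
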