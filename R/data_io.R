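# File formats, the mRNA scanning front-end, and the synthetic-data
# generator. Coordinates in user-facing output are 1-based inclusive; the
# input mRNA is taken as the sense strand.

#' Validate and normalize an siRNA record table
#'
#' @param records data frame with at least \code{antisense}; optional
#'   \code{id}, \code{target_site}, \code{efficacy}, \code{accessibility},
#'   \code{source}.
#' @param require_efficacy error if efficacy is absent or non-finite.
#' @return normalized data frame with an \code{id} column.
#' @export
as_sirna_records <- function(records, require_efficacy = FALSE) {
  if (!is.data.frame(records) || !"antisense" %in% names(records)) {
    stop("records must be a data frame with an 'antisense' column",
         call. = FALSE)
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  records$antisense <- as_sirna(records$antisense)
  if (!"id" %in% names(records)) {
    records$id <- sprintf("sirna_%04d", seq_len(nrow(records)))
  }
  records$id <- as.character(records$id)
  if ("target_site" %in% names(records)) {
    has <- !is.na(records$target_site)
    records$target_site[has] <- as_rna(records$target_site[has], "target site")
  }
  if (require_efficacy) {
    if (!"efficacy" %in% names(records)) {
      stop("records must have an 'efficacy' column", call. = FALSE)
    }
    if (!is.numeric(records$efficacy) || any(!is.finite(records$efficacy))) {
      stop("efficacies must be finite numbers", call. = FALSE)
    }
  }
  records
}

#' Read sequences from a FASTA file
#'
#' Parsing is delegated to \pkg{Biostrings}; DNA or RNA alphabet is
#' accepted and T is mapped to U. Records whose sequence contains any other
#' character are rejected with a warning naming the record, not a hard
#' error.
#'
#' @param path FASTA file.
#' @return data frame with columns \code{id}, \code{seq} (RNA alphabet).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(cnd) {
    stop("malformed FASTA in ", path, ": ", conditionMessage(cnd),
         call. = FALSE)
  })
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  keep <- rep(TRUE, length(ids))
  out_seq <- character(length(ids))
  for (i in seq_along(ids)) {
    res <- tryCatch(as_rna(seqs[i], what = paste0("record '", ids[i], "'")),
                    error = function(cnd) cnd)
    if (inherits(res, "error")) {
      warning("skipping FASTA ", conditionMessage(res), call. = FALSE)
      keep[i] <- FALSE
    } else if (!nzchar(res)) {
      warning("skipping empty FASTA record '", ids[i], "'", call. = FALSE)
      keep[i] <- FALSE
    } else {
      out_seq[i] <- res
    }
  }
  data.frame(id = ids[keep], seq = out_seq[keep], stringsAsFactors = FALSE)
}

#' Read / write an siRNA training table
#'
#' TSV with columns \code{id}, \code{antisense}, optional
#' \code{target_site}, \code{efficacy} (normalized inhibition, a fraction),
#' \code{accessibility}. Parse errors name the offending row.
#'
#' @param path TSV file.
#' @return data frame of siRNA records.
#' @export
read_sirna_table <- function(path) {
  if (!file.exists(path)) stop("siRNA table not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!"antisense" %in% names(tab)) {
    stop("siRNA table must have an 'antisense' column", call. = FALSE)
  }
  for (col in c("efficacy", "accessibility")) {
    if (col %in% names(tab)) {
      num <- suppressWarnings(as.numeric(tab[[col]]))
      bad <- which(is.na(num) & !is.na(tab[[col]]) & nzchar(tab[[col]]))
      if (length(bad)) {
        stop("non-numeric ", col, " in row ", bad[1], " of ", path,
             call. = FALSE)
      }
      tab[[col]] <- num
    }
  }
  as_sirna_records(tab)
}

#' @rdname read_sirna_table
#' @param records record data frame to write.
#' @export
write_sirna_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a ranked candidate table
#'
#' TSV with the columns rank, antisense, mutations, mismatches, target_site,
#' position_in_mrna, accessibility, e_pred, me; absent fields are written as
#' NA so the layout is stable across the scan and mutate workflows.
#'
#' @param candidates data frame (from \code{\link{rank_mutants}} or
#'   \code{\link{scan_mrna}}).
#' @param path output TSV file.
#' @export
write_candidates <- function(candidates, path) {
  cols <- c("rank", "antisense", "mutations", "mismatches", "target_site",
            "position_in_mrna", "accessibility", "e_pred", "me")
  for (col in setdiff(cols, names(candidates))) candidates[[col]] <- NA
  utils::write.table(candidates[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Scan an mRNA for effective complementary siRNAs
#'
#' Slides a window of the model's siRNA length along the sense-strand mRNA;
#' for each window the antisense candidate is the RNA reverse complement,
#' whose efficacy is predicted from its sequence (plus the site's
#' accessibility when the model uses that feature or a backend is given).
#' Output is sorted by predicted efficacy, descending. Window start
#' positions are 1-based inclusive.
#'
#' @param mrna mRNA sequence (sense strand; DNA alphabet accepted).
#' @param model a \code{sirna_model}.
#' @param params \code{\link{accessibility_params}}.
#' @param backend optional accessibility backend; required if the model's
#'   encoding spec includes the \code{accessibility} feature.
#' @return data frame with columns \code{rank}, \code{position_in_mrna},
#'   \code{target_site}, \code{antisense}, \code{accessibility},
#'   \code{e_pred}.
#' @export
scan_mrna <- function(mrna, model, params = accessibility_params(),
                      backend = NULL) {
  mrna <- as_rna(mrna, what = "mRNA")
  stopifnot(inherits(model, "sirna_model"))
  L <- model$meta$siRNA_length
  n <- nchar(mrna)
  if (n < L) {
    stop("mRNA (", n, " nt) shorter than the siRNA window (", L, " nt)",
         call. = FALSE)
  }
  starts <- seq_len(n - L + 1L)
  sites <- substring(mrna, starts, starts + L - 1L)
  antisense <- rna_revcomp(sites)
  needs_acc <- !is.null(model$spec) && "accessibility" %in% model$spec$encoders
  acc <- if (!is.null(backend)) {
    site_accessibility(mrna, starts, L, params, backend)
  } else if (needs_acc) {
    stop("model uses the accessibility feature but no backend was supplied",
         call. = FALSE)
  } else rep(NA_real_, length(starts))
  e_pred <- predict_efficacy(model, antisense,
                             accessibility = if (needs_acc) acc else NULL)
  out <- data.frame(position_in_mrna = starts, target_site = sites,
                    antisense = antisense, accessibility = acc,
                    e_pred = e_pred, stringsAsFactors = FALSE)
  out <- out[order(-out$e_pred, out$position_in_mrna), ]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Synthetic siRNA efficacy data with a planted signal
#'
#' Draws i.i.d. uniform random RNA sequences and assigns each an efficacy
#' from a planted linear model over its mononucleotide-composition and
#' positional one-hot features, plus Gaussian noise:
#' \code{efficacy = w . x + offset + N(0, noise_sd)}. The planted weights
#' are returned so recovery experiments can compare against ground truth.
#' Defaults emulate the scale of published efficacy screens: a few thousand
#' sequences would carry fractional efficacies mostly in [0, 1] with
#' positional effects dominating.
#'
#' @param n number of records.
#' @param length siRNA length (19 or 21).
#' @param seed integer seed; same seed, same output.
#' @param weight_scale sd of the planted per-feature weights.
#' @param noise_sd sd of the additive Gaussian noise (efficacy units).
#' @param offset intercept of the planted model.
#' @return list with \code{records} (data frame: id, antisense, efficacy,
#'   source) and \code{weights} (named numeric vector).
#' @export
generate_synthetic <- function(n, length = 19L, seed = 1L,
                               weight_scale = 0.05, noise_sd = 0.05,
                               offset = 0.5) {
  stopifnot(n >= 1L, length %in% c(19L, 21L))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(RNA_BASES, length, replace = TRUE), collapse = "")
  }, character(1))
  spec <- encoding_spec(c("mono", "binary"))
  x <- encode_features(seqs, spec)
  w <- stats::rnorm(ncol(x), sd = weight_scale)
  names(w) <- colnames(x)
  eff <- as.numeric(x %*% w) + offset + stats::rnorm(n, sd = noise_sd)
  records <- data.frame(id = sprintf("syn_%05d", seq_len(n)),
                        antisense = seqs, efficacy = eff,
                        source = "synthetic", stringsAsFactors = FALSE)
  list(records = records, weights = w)
}
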