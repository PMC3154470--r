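# Target-site accessibility: probability that a u-nt stretch of the mRNA
# around the target site is unpaired in the thermodynamic ensemble.
#
# Folding is delegated to a pluggable backend; the package never computes a
# partition function itself. Backends:
#   * backend_constant(p)        -- fixed value, for injection in tests
#   * backend_profile(profile)   -- precomputed RNAplfold "_lunp" output
#   * backend_rnaplfold()        -- shells out to an RNAplfold executable
# The u-nt stretch is anchored to the 3' end of the target site: the value
# reported for a site is P(unpaired) of the u-mer ending at the site's last
# base (RNAplfold rows index stretch END positions).

#' Accessibility window parameters
#'
#' @param W folding window size in nt (default 80).
#' @param L maximum base-pair span in nt (default 40).
#' @param u length of the unpaired stretch whose probability is reported
#'   (default 16).
#' @return object of class \code{accessibility_params}.
#' @export
accessibility_params <- function(W = 80L, L = 40L, u = 16L) {
  W <- as.integer(W); L <- as.integer(L); u <- as.integer(u)
  if (any(is.na(c(W, L, u))) || u <= 0L || u > L || L > W) {
    stop("require 0 < u <= L <= W", call. = FALSE)
  }
  structure(list(W = W, L = L, u = u), class = "accessibility_params")
}

#' Constant accessibility backend
#'
#' Returns the same probability for every query; useful for dependency
#' injection in tests and for running the pipeline without a folding engine.
#'
#' @param p probability in \code{[0, 1]}.
#' @return an accessibility backend function.
#' @export
backend_constant <- function(p) {
  stopifnot(is.numeric(p), length(p) == 1L, p >= 0, p <= 1)
  structure(function(mrna, end_pos, u) rep(p, length(end_pos)),
            class = c("accessibility_backend", "function"),
            label = sprintf("constant(%g)", p))
}

#' Read an RNAplfold unpaired-probability profile
#'
#' Parses the tab-separated "_lunp" output of RNAplfold: comment lines
#' starting with \code{#}, then one row per sequence position \code{i} with
#' columns for stretch lengths \code{u = 1..U}; entry \code{(i, u)} is the
#' probability that the u-mer ending at position i is unpaired
#' (\code{NA} where \code{i < u}).
#'
#' @param path path to a \code{_lunp} file.
#' @return numeric matrix, rows = end positions, columns = stretch lengths.
#' @export
read_lunp <- function(path) {
  if (!file.exists(path)) stop("lunp file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (!length(lines)) stop("lunp file has no data rows: ", path, call. = FALSE)
  rows <- strsplit(lines, "\t", fixed = TRUE)
  ncol_u <- max(lengths(rows)) - 1L
  m <- matrix(NA_real_, nrow = length(rows), ncol = ncol_u)
  pos <- integer(length(rows))
  for (i in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(rows[[i]]))
    pos[i] <- as.integer(v[1])
    vals <- v[-1]
    m[i, seq_along(vals)] <- vals
  }
  m <- m[order(pos), , drop = FALSE]
  rownames(m) <- sort(pos)
  colnames(m) <- seq_len(ncol_u)
  m
}

#' Precomputed-profile accessibility backend
#'
#' @param profile matrix from \code{\link{read_lunp}} (or of the same shape).
#' @return an accessibility backend function.
#' @export
backend_profile <- function(profile) {
  stopifnot(is.matrix(profile))
  structure(function(mrna, end_pos, u) {
    if (u > ncol(profile)) {
      stop("profile was computed with max stretch ", ncol(profile),
           " < u = ", u, call. = FALSE)
    }
    if (any(end_pos > nrow(profile))) {
      stop("profile covers ", nrow(profile),
           " positions; query end position out of range", call. = FALSE)
    }
    profile[end_pos, u]
  }, class = c("accessibility_backend", "function"), label = "profile")
}

#' RNAplfold accessibility backend
#'
#' Runs the RNAplfold executable on the query mRNA (once per distinct
#' sequence; results are cached) and reads back the unpaired-probability
#' profile. Requires RNAplfold (ViennaRNA) on the PATH.
#'
#' @param exe name or path of the RNAplfold executable.
#' @param params \code{\link{accessibility_params}} used for the run.
#' @return an accessibility backend function.
#' @export
backend_rnaplfold <- function(exe = "RNAplfold",
                              params = accessibility_params()) {
  if (!nzchar(Sys.which(exe))) {
    stop("RNAplfold executable '", exe, "' not found on PATH; supply a ",
         "precomputed profile via backend_profile() instead", call. = FALSE)
  }
  cache <- new.env(parent = emptyenv())
  structure(function(mrna, end_pos, u) {
    if (u > params$u) {
      stop("backend configured with max stretch u = ", params$u,
           " < requested ", u, call. = FALSE)
    }
    key <- paste0("seq", substr(mrna, 1, 20), nchar(mrna))
    if (!exists(key, envir = cache, inherits = FALSE)) {
      dir <- tempfile("rnaplfold_")
      dir.create(dir)
      old <- setwd(dir); on.exit(setwd(old), add = TRUE)
      writeLines(c(">query", mrna), "input.fa")
      status <- system2(exe,
                        c("-W", params$W, "-L", params$L, "-u", params$u),
                        stdin = "input.fa", stdout = FALSE, stderr = FALSE)
      if (status != 0L) stop("RNAplfold failed with status ", status,
                             call. = FALSE)
      lunp <- list.files(dir, pattern = "_lunp$", full.names = TRUE)
      if (length(lunp) != 1L) stop("RNAplfold produced no _lunp output",
                                   call. = FALSE)
      assign(key, read_lunp(lunp), envir = cache)
    }
    profile <- get(key, envir = cache)
    backend_profile(profile)(mrna, end_pos, u)
  }, class = c("accessibility_backend", "function"), label = "rnaplfold")
}

#' Accessibility of one target site
#'
#' Probability that the u-nt stretch ending at the site's 3' end is unpaired,
#' obtained from the supplied backend. No silent default exists: without a
#' backend this is a configuration error.
#'
#' @param mrna the mRNA sequence (sense strand, RNA alphabet).
#' @param site_start 1-based start of the target site within \code{mrna}.
#' @param site_len site length in nt (19 or 21 for siRNA use).
#' @param params \code{\link{accessibility_params}}.
#' @param backend an accessibility backend (\code{\link{backend_constant}},
#'   \code{\link{backend_profile}} or \code{\link{backend_rnaplfold}}).
#' @return probability in \code{[0, 1]}.
#' @export
site_accessibility <- function(mrna, site_start, site_len,
                               params = accessibility_params(),
                               backend = NULL) {
  mrna <- as_rna(mrna, what = "mRNA")
  if (is.null(backend)) {
    stop("no accessibility backend configured; pass backend_constant(), ",
         "backend_profile() or backend_rnaplfold()", call. = FALSE)
  }
  stopifnot(inherits(params, "accessibility_params"))
  site_start <- as.integer(site_start)
  site_end <- site_start + as.integer(site_len) - 1L
  if (any(site_start < 1L) || any(site_end > nchar(mrna))) {
    stop("target site outside mRNA bounds", call. = FALSE)
  }
  p <- as.numeric(backend(mrna, site_end, params$u))
  bad <- is.finite(p) & (p < 0 | p > 1)
  if (any(bad)) stop("backend returned probability outside [0, 1]",
                     call. = FALSE)
  p
}
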