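# Mismatch penalty tables
#
# A penalty table holds the efficacy deductions applied per siRNA:target
# mismatch: single-mismatch entries keyed by (position, siRNA base, target
# base), optional double-mismatch entries keyed by the unordered position
# pair plus both identities, and per-position averages used as fallback when
# an identity (or a >2-mismatch pattern) is absent from the experimental
# data. Positions are 1..19 on the antisense, 5'->3'.

MAX_PENALTY_POS <- 19L

# the 12 mismatch identities at one position: each siRNA base against the 3
# target bases that are not its Watson-Crick partner
mismatch_identities <- function() {
  out <- expand.grid(sirna_base = RNA_BASES, target_base = RNA_BASES,
                     stringsAsFactors = FALSE)
  out[out$target_base != RNA_COMPLEMENT[out$sirna_base], , drop = FALSE]
}

single_key <- function(position, sirna_base, target_base) {
  paste(position, sirna_base, target_base, sep = "|")
}
double_key <- function(pos1, pos2, id1, id2) {
  # unordered position pair: canonicalize so pos1 < pos2
  swap <- pos1 > pos2
  p1 <- ifelse(swap, pos2, pos1); p2 <- ifelse(swap, pos1, pos2)
  i1 <- ifelse(swap, id2, id1);   i2 <- ifelse(swap, id1, id2)
  paste(p1, p2, i1, i2, sep = "|")
}

#' Construct a mismatch penalty table
#'
#' @param singles data frame with columns \code{position},
#'   \code{sirna_base}, \code{target_base}, \code{penalty} (efficacy units).
#' @param doubles optional data frame with columns \code{pos1}, \code{pos2},
#'   \code{sirna_base1}, \code{target_base1}, \code{sirna_base2},
#'   \code{target_base2}, \code{penalty}.
#' @param position_avg optional named numeric vector (names = positions)
#'   overriding the per-position averages; by default they are derived from
#'   \code{singles} by averaging the available identities at each position.
#' @return object of class \code{penalty_table}.
#' @export
penalty_table <- function(singles, doubles = NULL, position_avg = NULL) {
  req <- c("position", "sirna_base", "target_base", "penalty")
  if (!is.data.frame(singles) || !all(req %in% names(singles))) {
    stop("singles must be a data frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  singles$position <- as.integer(singles$position)
  singles$sirna_base <- as_rna(singles$sirna_base)
  singles$target_base <- as_rna(singles$target_base)
  if (any(singles$position < 1L | singles$position > MAX_PENALTY_POS)) {
    stop("single-mismatch positions must lie in 1..", MAX_PENALTY_POS,
         call. = FALSE)
  }
  if (any(!is.finite(singles$penalty))) {
    stop("penalties must be finite", call. = FALSE)
  }
  if (!is.null(doubles)) {
    reqd <- c("pos1", "pos2", "sirna_base1", "target_base1",
              "sirna_base2", "target_base2", "penalty")
    if (!is.data.frame(doubles) || !all(reqd %in% names(doubles))) {
      stop("doubles must have columns ", paste(reqd, collapse = ", "),
           call. = FALSE)
    }
    doubles$pos1 <- as.integer(doubles$pos1)
    doubles$pos2 <- as.integer(doubles$pos2)
    if (any(doubles$pos1 == doubles$pos2)) {
      stop("double-mismatch positions must be distinct", call. = FALSE)
    }
    if (any(!is.finite(doubles$penalty))) {
      stop("penalties must be finite", call. = FALSE)
    }
    for (col in c("sirna_base1", "target_base1", "sirna_base2", "target_base2")) {
      doubles[[col]] <- as_rna(doubles[[col]])
    }
  }
  derived_avg <- tapply(singles$penalty, singles$position, mean)
  avg <- stats::setNames(as.numeric(derived_avg), names(derived_avg))
  if (!is.null(position_avg)) {
    if (is.null(names(position_avg))) {
      stop("position_avg must be named by position", call. = FALSE)
    }
    avg[names(position_avg)] <- as.numeric(position_avg)
  }
  singles_map <- stats::setNames(
    singles$penalty,
    single_key(singles$position, singles$sirna_base, singles$target_base))
  doubles_map <- if (!is.null(doubles) && nrow(doubles)) {
    stats::setNames(
      doubles$penalty,
      double_key(doubles$pos1, doubles$pos2,
                 paste0(doubles$sirna_base1, ":", doubles$target_base1),
                 paste0(doubles$sirna_base2, ":", doubles$target_base2)))
  } else stats::setNames(numeric(0), character(0))
  structure(list(singles = singles, doubles = doubles,
                 singles_map = singles_map, doubles_map = doubles_map,
                 position_avg = avg),
            class = "penalty_table")
}

#' @export
print.penalty_table <- function(x, ...) {
  cat(sprintf("penalty_table: %d single entries over %d positions, %d double entries\n",
              nrow(x$singles), length(unique(x$singles$position)),
              if (is.null(x$doubles)) 0L else nrow(x$doubles)))
  invisible(x)
}

#' Read / write a penalty table TSV
#'
#' One TSV holds both single and double entries: columns \code{kind}
#' (\code{single} or \code{double}), \code{pos1}, \code{pos2} (empty for
#' singles), \code{sirna_base1}, \code{target_base1}, \code{sirna_base2},
#' \code{target_base2} (empty for singles), \code{penalty}. An optional
#' second TSV with columns \code{position}, \code{penalty} overrides the
#' derived per-position averages.
#'
#' @param path TSV file path.
#' @param position_avg_path optional TSV overriding position averages.
#' @return \code{read_penalty_table}: a \code{\link{penalty_table}};
#'   \code{write_penalty_table}: \code{path}, invisibly.
#' @export
read_penalty_table <- function(path, position_avg_path = NULL) {
  if (!file.exists(path)) stop("penalty table not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  req <- c("kind", "pos1", "pos2", "sirna_base1", "target_base1",
           "sirna_base2", "target_base2", "penalty")
  if (!all(req %in% names(tab))) {
    stop("penalty TSV must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(tab$penalty)) {
    bad <- which(is.na(suppressWarnings(as.numeric(tab$penalty))))[1]
    stop("non-numeric penalty in row ", bad, " of ", path, call. = FALSE)
  }
  s <- tab[tab$kind == "single", , drop = FALSE]
  d <- tab[tab$kind == "double", , drop = FALSE]
  singles <- data.frame(position = s$pos1, sirna_base = s$sirna_base1,
                        target_base = s$target_base1, penalty = s$penalty,
                        stringsAsFactors = FALSE)
  doubles <- if (nrow(d)) {
    data.frame(pos1 = d$pos1, pos2 = d$pos2,
               sirna_base1 = d$sirna_base1, target_base1 = d$target_base1,
               sirna_base2 = d$sirna_base2, target_base2 = d$target_base2,
               penalty = d$penalty, stringsAsFactors = FALSE)
  } else NULL
  avg <- NULL
  if (!is.null(position_avg_path)) {
    pa <- utils::read.delim(position_avg_path, stringsAsFactors = FALSE)
    if (!all(c("position", "penalty") %in% names(pa))) {
      stop("position-average TSV must have columns position, penalty",
           call. = FALSE)
    }
    avg <- stats::setNames(pa$penalty, pa$position)
  }
  penalty_table(singles, doubles, position_avg = avg)
}

#' @rdname read_penalty_table
#' @param table a \code{\link{penalty_table}} to write.
#' @export
write_penalty_table <- function(table, path) {
  stopifnot(inherits(table, "penalty_table"))
  s <- table$singles
  rows <- data.frame(kind = "single", pos1 = s$position, pos2 = NA_integer_,
                     sirna_base1 = s$sirna_base, target_base1 = s$target_base,
                     sirna_base2 = NA_character_, target_base2 = NA_character_,
                     penalty = s$penalty, stringsAsFactors = FALSE)
  if (!is.null(table$doubles) && nrow(table$doubles)) {
    d <- table$doubles
    rows <- rbind(rows, data.frame(
      kind = "double", pos1 = d$pos1, pos2 = d$pos2,
      sirna_base1 = d$sirna_base1, target_base1 = d$target_base1,
      sirna_base2 = d$sirna_base2, target_base2 = d$target_base2,
      penalty = d$penalty, stringsAsFactors = FALSE))
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Heuristic synthetic penalty table
#'
#' The experimentally measured mismatch-tolerance values this scoring scheme
#' was built on are not publicly printed, so the package ships a clearly
#' synthetic stand-in constructed from the published tolerance tiers:
#' positions 5-11 carry the largest penalties (mismatches there abolish
#' silencing), positions 1, 2, 18 and 19 the smallest (well tolerated), the
#' rest moderate; the well-tolerated identities A:C, G:U and U:G
#' (siRNA:target) are discounted and the poorly tolerated A:G inflated. One
#' experimentally published value is pinned exactly: a U:G mismatch at
#' position 1 costs 0.066 efficacy units. A seeded multiplicative jitter
#' keeps entries distinct. Users with access to real mismatch-tolerance
#' measurements should load them with \code{\link{read_penalty_table}}.
#'
#' @param seed integer seed for the jitter.
#' @param tiers list of tier magnitudes \code{high_tolerance},
#'   \code{moderate}, \code{low_tolerance} (efficacy units).
#' @return a \code{\link{penalty_table}} with 19 x 12 = 228 single entries.
#' @export
generate_synthetic_penalties <- function(seed = 1L,
                                         tiers = list(high_tolerance = 0.08,
                                                      moderate = 0.25,
                                                      low_tolerance = 0.55)) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  ids <- mismatch_identities()
  grid <- merge(data.frame(position = 1:MAX_PENALTY_POS), ids, by = NULL)
  grid <- grid[order(grid$position, grid$sirna_base, grid$target_base), ]
  tier_of <- function(pos) {
    ifelse(pos %in% c(1L, 2L, 18L, 19L), tiers$high_tolerance,
           ifelse(pos %in% 5:11, tiers$low_tolerance, tiers$moderate))
  }
  identity_mult <- function(s, t) {
    id <- paste0(s, ":", t)
    ifelse(id %in% c("A:C", "G:U", "U:G"), 0.4,
           ifelse(id == "A:G", 1.25, 1.0))
  }
  base <- tier_of(grid$position) * identity_mult(grid$sirna_base,
                                                 grid$target_base)
  jitter <- stats::runif(nrow(grid), 0.9, 1.1)
  grid$penalty <- pmax(base * jitter, 0)
  # pin the one published experimental value: U:G at position 1 -> 0.066
  pin <- grid$position == 1L & grid$sirna_base == "U" & grid$target_base == "G"
  grid$penalty[pin] <- 0.066
  rownames(grid) <- NULL
  penalty_table(grid)
}
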