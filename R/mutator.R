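# Mutant siRNA design: mismatch detection, enumeration, mismatch efficacy
# (ME) scoring, ranking, and allele discrimination.
#
# ME = complementary predicted efficacy - sum of mismatch penalties.
# The predicted efficacy of a mutant is computed from the mutant antisense
# sequence alone (RISC loading depends on the duplex, not the target);
# the target sequence enters only through the mismatch list.

#' Detect siRNA:target mismatches
#'
#' Both sequences are given 5'->3'; antisense position \code{i} pairs with
#' target position \code{L + 1 - i}. Watson-Crick pairs (A:U, U:A, G:C, C:G)
#' are matches; everything else, including the G:U wobble, is reported as a
#' mismatch in siRNA:target notation.
#'
#' @param antisense,target equal-length RNA sequences, both 5'->3'.
#' @return data frame with columns \code{position} (1-based on the
#'   antisense), \code{sirna_base}, \code{target_base}; zero rows if fully
#'   complementary.
#' @examples
#' pairing_mismatches("CAGUGGAAAGUACAUCAGA", "UCUGAUGUACUUUCCACUG")  # none
#' pairing_mismatches("UAGUGGAAAGUACAUCAGA", "UCUGAUGUACUUUCCACUG")  # 1 U:G
#' @export
pairing_mismatches <- function(antisense, target) {
  antisense <- as_rna(antisense, "antisense")
  target <- as_rna(target, "target")
  if (nchar(antisense) != nchar(target)) {
    stop("antisense and target must have equal length", call. = FALSE)
  }
  a <- seq_bases(antisense)
  t <- rev(seq_bases(target))
  mm <- which(RNA_COMPLEMENT[a] != t)
  data.frame(position = mm,
             sirna_base = a[mm],
             target_base = t[mm],
             stringsAsFactors = FALSE)
}

#' Enumerate all single-base mutants of a 19-nt antisense
#'
#' Every position substituted with each of the three other bases:
#' 3 x 19 = 57 distinct mutants, ordered by position then by replacement
#' base (A < C < G < U). The original sequence is not included.
#'
#' @param antisense a 19-nt antisense sequence.
#' @param lengths accepted sequence lengths; the design workflow uses 19 nt,
#'   but any length can be enumerated (count is always \code{3 * L}).
#' @return data frame with columns \code{position}, \code{from}, \code{to},
#'   \code{antisense} (the mutant sequence).
#' @export
enumerate_single_mutants <- function(antisense, lengths = 19L) {
  antisense <- as_sirna(antisense, lengths = lengths)
  b <- seq_bases(antisense)
  out <- do.call(rbind, lapply(seq_along(b), function(pos) {
    subs <- setdiff(RNA_BASES, b[pos])
    data.frame(position = pos, from = b[pos], to = subs,
               stringsAsFactors = FALSE)
  }))
  out$antisense <- vapply(seq_len(nrow(out)), function(i) {
    m <- b; m[out$position[i]] <- out$to[i]
    paste(m, collapse = "")
  }, character(1))
  out
}

#' Enumerate all double-base mutants of a 19-nt antisense
#'
#' Every unordered position pair with every non-identity base choice at both
#' positions: \code{choose(19, 2) * 9 = 1539} candidates, ordered by
#' (pos1, pos2, to1, to2).
#'
#' @param antisense a 19-nt antisense sequence.
#' @param lengths accepted sequence lengths (count is always
#'   \code{9 * choose(L, 2)}).
#' @return data frame with columns \code{pos1}, \code{pos2}, \code{from1},
#'   \code{to1}, \code{from2}, \code{to2}, \code{antisense}.
#' @export
enumerate_double_mutants <- function(antisense, lengths = 19L) {
  antisense <- as_sirna(antisense, lengths = lengths)
  b <- seq_bases(antisense)
  L <- length(b)
  pairs <- utils::combn(L, 2L)
  rows <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    p1 <- pairs[1, k]; p2 <- pairs[2, k]
    subs1 <- setdiff(RNA_BASES, b[p1])
    subs2 <- setdiff(RNA_BASES, b[p2])
    g <- expand.grid(to2 = subs2, to1 = subs1, stringsAsFactors = FALSE)
    rows[[k]] <- data.frame(pos1 = p1, pos2 = p2,
                            from1 = b[p1], to1 = g$to1,
                            from2 = b[p2], to2 = g$to2,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$pos1, out$pos2, out$to1, out$to2), ]
  rownames(out) <- NULL
  out$antisense <- vapply(seq_len(nrow(out)), function(i) {
    m <- b
    m[out$pos1[i]] <- out$to1[i]
    m[out$pos2[i]] <- out$to2[i]
    paste(m, collapse = "")
  }, character(1))
  out
}

#' Total mismatch penalty with provenance
#'
#' Applies the deduction rules: no mismatches cost nothing; a single
#' mismatch uses its exact (position, identity) entry, falling back to the
#' position average when the identity is absent; two mismatches use the
#' exact double entry when present, otherwise the sum of the two position
#' averages; three or more mismatches always use position averages. The
#' provenance table records which rule fired, covering every mismatch
#' exactly once.
#'
#' @param mismatches data frame from \code{\link{pairing_mismatches}}.
#' @param table a \code{\link{penalty_table}}.
#' @return list with \code{total} (numeric) and \code{provenance}
#'   (data frame with columns \code{positions}, \code{identities},
#'   \code{rule}, \code{penalty}).
#' @export
lookup_penalty <- function(mismatches, table) {
  stopifnot(inherits(table, "penalty_table"))
  empty_prov <- data.frame(positions = character(0), identities = character(0),
                           rule = character(0), penalty = numeric(0),
                           stringsAsFactors = FALSE)
  if (is.null(mismatches) || nrow(mismatches) == 0L) {
    return(list(total = 0, provenance = empty_prov))
  }
  if (any(mismatches$position < 1L | mismatches$position > MAX_PENALTY_POS)) {
    stop("mismatch positions must lie in 1..", MAX_PENALTY_POS, call. = FALSE)
  }
  avg_of <- function(pos) {
    v <- table$position_avg[as.character(pos)]
    if (any(is.na(v))) {
      stop("no position average available for position ",
           paste(pos[is.na(v)], collapse = ", "), call. = FALSE)
    }
    as.numeric(v)
  }
  ident <- paste0(mismatches$sirna_base, ":", mismatches$target_base)
  n <- nrow(mismatches)

  avg_fallback <- function(idx) {
    data.frame(positions = as.character(mismatches$position[idx]),
               identities = ident[idx],
               rule = "position_avg",
               penalty = avg_of(mismatches$position[idx]),
               stringsAsFactors = FALSE)
  }

  prov <- if (n == 1L) {
    key <- single_key(mismatches$position, mismatches$sirna_base,
                      mismatches$target_base)
    if (key %in% names(table$singles_map)) {
      data.frame(positions = as.character(mismatches$position),
                 identities = ident, rule = "single_exact",
                 penalty = as.numeric(table$singles_map[key]),
                 stringsAsFactors = FALSE)
    } else avg_fallback(1L)
  } else if (n == 2L) {
    key <- double_key(mismatches$position[1], mismatches$position[2],
                      ident[1], ident[2])
    if (key %in% names(table$doubles_map)) {
      data.frame(positions = paste(sort(mismatches$position), collapse = "+"),
                 identities = paste(ident[order(mismatches$position)],
                                    collapse = "/"),
                 rule = "double_exact",
                 penalty = as.numeric(table$doubles_map[key]),
                 stringsAsFactors = FALSE)
    } else avg_fallback(1:2)
  } else {
    avg_fallback(seq_len(n))
  }
  list(total = sum(prov$penalty), provenance = prov)
}

#' Mismatch efficacy (ME)
#'
#' The overall efficacy of a mutant siRNA against a fixed target: the
#' predicted efficacy it would have if fully complementary, minus the summed
#' penalty of every siRNA:target mismatch. Not clipped; ME below 0 or above
#' 1 is reported as computed.
#'
#' @param e_pred predicted efficacy of the (mutant) antisense as a
#'   complementary siRNA.
#' @param mismatches data frame from \code{\link{pairing_mismatches}}.
#' @param table a \code{\link{penalty_table}}.
#' @return single numeric ME value.
#' @examples
#' tab <- penalty_table(data.frame(position = 1, sirna_base = "U",
#'                                 target_base = "G", penalty = 0.066))
#' mm <- pairing_mismatches("UAGUGGAAAGUACAUCAGA", "UCUGAUGUACUUUCCACUG")
#' mismatch_efficacy(0.776, mm, tab)  # 0.776 - 0.066 = 0.710
#' @export
mismatch_efficacy <- function(e_pred, mismatches, table) {
  stopifnot(is.numeric(e_pred), length(e_pred) == 1L, is.finite(e_pred))
  e_pred - lookup_penalty(mismatches, table)$total
}

# compact string renderings for candidate tables
format_mutations <- function(position, from, to) {
  paste0(position, ":", from, ">", to)
}
format_mismatches <- function(mm) {
  if (nrow(mm) == 0L) return("")
  paste(paste0(mm$position, mm$sirna_base, ":", mm$target_base),
        collapse = ",")
}

#' Enumerate, score and rank mutant siRNAs
#'
#' Generates all single (or double) mutants of the antisense, predicts each
#' mutant's complementary efficacy from its sequence with the model, detects
#' its mismatches against the fixed original target, deducts penalties, and
#' sorts by ME. Ties keep enumeration order (position ascending, then
#' replacement base A < C < G < U), so the ranking is a total order and
#' reruns are identical.
#'
#' @param antisense 19-nt antisense sequence (the complementary design).
#' @param target 19-nt target site, 5'->3'.
#' @param model a \code{sirna_model} with siRNA length 19.
#' @param table a \code{\link{penalty_table}}.
#' @param depth \code{"single"} (57 candidates) or \code{"double"} (1539).
#' @param include_wildtype also score the unmutated antisense (rank among
#'   the candidates).
#' @param decreasing sort by ME descending (default); set \code{FALSE} to
#'   design deliberately low-efficacy siRNAs (e.g. against an off-target).
#' @return data frame with columns \code{rank}, \code{antisense},
#'   \code{mutations}, \code{n_mismatch}, \code{mismatches}, \code{e_pred},
#'   \code{me}.
#' @export
rank_mutants <- function(antisense, target, model, table,
                         depth = c("single", "double"),
                         include_wildtype = FALSE, decreasing = TRUE) {
  depth <- match.arg(depth)
  antisense <- as_sirna(antisense, lengths = 19L)
  target <- as_rna(target, "target")
  stopifnot(inherits(model, "sirna_model"))
  if (model$meta$siRNA_length != 19L) {
    stop("mutant design requires a 19-nt model", call. = FALSE)
  }
  cand <- if (depth == "single") {
    em <- enumerate_single_mutants(antisense)
    data.frame(antisense = em$antisense,
               mutations = format_mutations(em$position, em$from, em$to),
               stringsAsFactors = FALSE)
  } else {
    em <- enumerate_double_mutants(antisense)
    data.frame(antisense = em$antisense,
               mutations = paste(format_mutations(em$pos1, em$from1, em$to1),
                                 format_mutations(em$pos2, em$from2, em$to2),
                                 sep = ","),
               stringsAsFactors = FALSE)
  }
  if (include_wildtype) {
    cand <- rbind(data.frame(antisense = antisense, mutations = "",
                             stringsAsFactors = FALSE), cand)
  }
  cand$e_pred <- predict_efficacy(model, cand$antisense)
  mm_list <- lapply(cand$antisense, pairing_mismatches, target = target)
  cand$n_mismatch <- vapply(mm_list, nrow, integer(1))
  cand$mismatches <- vapply(mm_list, format_mismatches, character(1))
  cand$me <- vapply(seq_len(nrow(cand)), function(i) {
    mismatch_efficacy(cand$e_pred[i], mm_list[[i]], table)
  }, numeric(1))
  ord <- order(if (decreasing) -cand$me else cand$me, seq_len(nrow(cand)))
  cand <- cand[ord, ]
  cand <- cbind(rank = seq_len(nrow(cand)), cand)
  rownames(cand) <- NULL
  cand
}

#' Allele-discrimination score
#'
#' For SNP-selective silencing: one siRNA is scored against both the mutant
#' (disease) allele and the wild-type target from the same complementary
#' predicted efficacy. The discrimination score is
#' \code{delta = me_mutant - me_wt}; larger values mean the siRNA silences
#' the mutant transcript while sparing wild type.
#'
#' @param antisense 19-nt antisense sequence.
#' @param mutant_target,wt_target equal-length target sites differing at the
#'   SNP position(s), 5'->3'.
#' @param model a \code{sirna_model} (length 19).
#' @param table a \code{\link{penalty_table}}.
#' @return list with \code{e_pred}, \code{me_mutant}, \code{me_wt},
#'   \code{delta}, \code{mm_mutant}, \code{mm_wt}.
#' @export
allele_discrimination <- function(antisense, mutant_target, wt_target,
                                  model, table) {
  antisense <- as_sirna(antisense, lengths = 19L)
  mutant_target <- as_rna(mutant_target, "mutant target")
  wt_target <- as_rna(wt_target, "wild-type target")
  if (nchar(mutant_target) != nchar(wt_target)) {
    stop("targets must have equal length", call. = FALSE)
  }
  if (mutant_target == wt_target) {
    warning("mutant and wild-type targets are identical; delta is 0 by construction")
  }
  e_pred <- predict_efficacy(model, antisense)
  mm_mut <- pairing_mismatches(antisense, mutant_target)
  mm_wt <- pairing_mismatches(antisense, wt_target)
  me_mut <- mismatch_efficacy(e_pred, mm_mut, table)
  me_wt <- mismatch_efficacy(e_pred, mm_wt, table)
  list(e_pred = e_pred, me_mutant = me_mut, me_wt = me_wt,
       delta = me_mut - me_wt, mm_mutant = mm_mut, mm_wt = mm_wt)
}
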