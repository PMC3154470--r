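# Shared fixtures and independent brute-force oracles.

# Figure-style worked example: a fully complementary antisense/target pair
# and its position-1 C->U mutant, whose U:G mismatch costs 0.066 efficacy
# units on top of a complementary predicted efficacy of 0.776.
FIG_ANTISENSE <- "CAGUGGAAAGUACAUCAGA"
FIG_TARGET    <- "UCUGAUGUACUUUCCACUG"
FIG_MUTANT    <- "UAGUGGAAAGUACAUCAGA"
FIG_E_PRED    <- 0.776
FIG_PENALTY   <- 0.066
FIG_ME        <- 0.710

fixture_penalty_table <- function() {
  penalty_table(data.frame(position = 1L, sirna_base = "U",
                           target_base = "G", penalty = FIG_PENALTY,
                           stringsAsFactors = FALSE))
}

# fixture with the printed (1, U:G) entry plus a moderate placeholder
# identity at every position, so the full 57-mutant ranking has a position
# average to fall back on everywhere
workflow_penalty_table <- function() {
  singles <- rbind(
    data.frame(position = 1L, sirna_base = "U", target_base = "G",
               penalty = FIG_PENALTY, stringsAsFactors = FALSE),
    data.frame(position = 1:19, sirna_base = "A", target_base = "A",
               penalty = 0.25, stringsAsFactors = FALSE))
  penalty_table(singles)
}

# the 12 mismatch identities (siRNA base vs non-complementary target base)
mismatch_ids <- local({
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  g <- expand.grid(s = c("A", "C", "G", "U"), t = c("A", "C", "G", "U"),
                   stringsAsFactors = FALSE)
  g[g$t != comp[g$s], ]
})
mismatch_ids_s <- mismatch_ids$s
mismatch_ids_t <- mismatch_ids$t

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# oracle: count k-mers (possibly gapped with step `order`) by an explicit
# nested loop over start positions and alphabet enumeration
naive_tuple_composition <- function(seq, n, order = 1L) {
  b <- strsplit(seq, "")[[1]]
  L <- length(b)
  span <- (n - 1L) * order
  words <- character(0)
  for (i in seq_len(L - span)) {
    idx <- i + (0:(n - 1L)) * order
    words <- c(words, paste(b[idx], collapse = ""))
  }
  bases <- c("A", "C", "G", "U")
  lev <- bases
  if (n > 1) for (j in 2:n) lev <- as.vector(t(outer(lev, bases, paste0)))
  out <- numeric(length(lev))
  names(out) <- lev
  for (w in words) out[w] <- out[w] + 1
  out / length(words)
}

# oracle: regression metrics from their definitions, computed stepwise
naive_metrics <- function(pred, actual) {
  n <- length(pred)
  mp <- sum(pred) / n; ma <- sum(actual) / n
  R <- sum((pred - mp) * (actual - ma)) /
    sqrt(sum((pred - mp)^2) * sum((actual - ma)^2))
  ss_res <- 0; abs_err <- 0; sq_err <- 0
  for (i in seq_len(n)) {
    e <- actual[i] - pred[i]
    ss_res <- ss_res + e^2
    abs_err <- abs_err + abs(e)
    sq_err <- sq_err + e^2
  }
  list(R = R, R2 = 1 - ss_res / sum((actual - ma)^2),
       MAE = abs_err / n, RMSE = sqrt(sq_err / n))
}

# oracle: count siRNA:target mismatches by explicitly complementing the
# target and comparing strings
naive_mismatch_count <- function(antisense, target) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  a <- strsplit(antisense, "")[[1]]
  t <- strsplit(target, "")[[1]]
  sum(a != comp[rev(t)])
}

# oracle: enumerate all distinct single/double substitution variants of a
# sequence by generating every string and deduplicating
naive_variant_count <- function(seq, depth) {
  b <- strsplit(seq, "")[[1]]
  bases <- c("A", "C", "G", "U")
  out <- character(0)
  if (depth == 1L) {
    for (i in seq_along(b)) for (x in bases) {
      if (x != b[i]) { m <- b; m[i] <- x; out <- c(out, paste(m, collapse = "")) }
    }
  } else {
    for (i in seq_along(b)) for (j in seq_along(b)) {
      if (i >= j) next
      for (x in bases) for (y in bases) {
        if (x == b[i] || y == b[j]) next
        m <- b; m[i] <- x; m[j] <- y
        out <- c(out, paste(m, collapse = ""))
      }
    }
  }
  length(unique(out))
}

# small trained model shared across tests (planted signal, quick to fit)
tiny_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      syn <- generate_synthetic(n = 120, length = 19L, seed = 101,
                                noise_sd = 0.05)
      cache <<- train_model(syn$records, training_set_id = "tiny_planted")
    }
    cache
  }
})
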