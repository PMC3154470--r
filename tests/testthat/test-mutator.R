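test_that("mismatch detection pairs antisense i with target L+1-i", {
  expect_equal(nrow(pairing_mismatches(FIG_ANTISENSE, FIG_TARGET)), 0)
  mm <- pairing_mismatches(FIG_MUTANT, FIG_TARGET)
  expect_equal(mm$position, 1L)
  expect_equal(mm$sirna_base, "U")
  expect_equal(mm$target_base, "G")
  # G:U wobble is a mismatch, not a pair
  expect_equal(nrow(pairing_mismatches("G", "U")), 1)
  expect_equal(nrow(pairing_mismatches("G", "C")), 0)
  expect_error(pairing_mismatches("ACGU", "ACG"), "equal length")
})

test_that("mismatch counts agree with a brute-force complement oracle", {
  set.seed(23)
  for (i in 1:100) {
    a <- random_rna(19)
    t <- random_rna(19)
    expect_equal(nrow(pairing_mismatches(a, t)), naive_mismatch_count(a, t))
  }
})

test_that("single-mutant enumeration yields 3L distinct non-wildtype variants", {
  em <- enumerate_single_mutants(FIG_ANTISENSE)
  expect_equal(nrow(em), 57)
  expect_false(any(duplicated(em$antisense)))
  expect_false(FIG_ANTISENSE %in% em$antisense)
  expect_true(all(nchar(em$antisense) == 19))
  # deterministic order: position ascending, replacement base A < C < G < U
  expect_equal(em$position[1:6], c(1L, 1L, 1L, 2L, 2L, 2L))
  expect_equal(em$to[1:3], c("A", "G", "U"))   # original base C skipped
  expect_error(enumerate_single_mutants(random_rna(21)), "19")
})

test_that("mutant counts match brute-force enumeration at several lengths", {
  set.seed(29)
  for (L in c(5L, 19L, 21L)) {
    s <- random_rna(L)
    em1 <- enumerate_single_mutants(s, lengths = L)
    expect_equal(nrow(em1), 3L * L)
    expect_equal(nrow(em1), naive_variant_count(s, 1L))
    em2 <- enumerate_double_mutants(s, lengths = L)
    expect_equal(nrow(em2), 9L * choose(L, 2))
    expect_equal(length(unique(em2$antisense)), naive_variant_count(s, 2L))
    expect_true(all(em2$pos1 < em2$pos2))
  }
  expect_equal(nrow(enumerate_double_mutants(FIG_ANTISENSE)), 1539)
})

test_that("penalty lookup applies the fallback rules with full provenance", {
  tab <- penalty_table(
    data.frame(position = c(1L, 4L, 4L, 11L),
               sirna_base = c("U", "A", "A", "C"),
               target_base = c("G", "C", "G", "C"),
               penalty = c(0.066, 0.10, 0.30, 0.50),
               stringsAsFactors = FALSE),
    doubles = data.frame(pos1 = 4L, pos2 = 11L,
                         sirna_base1 = "A", target_base1 = "C",
                         sirna_base2 = "C", target_base2 = "C",
                         penalty = 0.45, stringsAsFactors = FALSE))
  expect_equal(lookup_penalty(NULL, tab)$total, 0)
  no_mm <- pairing_mismatches(FIG_ANTISENSE, FIG_TARGET)
  expect_equal(lookup_penalty(no_mm, tab)$total, 0)

  one <- data.frame(position = 1L, sirna_base = "U", target_base = "G")
  r <- lookup_penalty(one, tab)
  expect_equal(r$total, 0.066)
  expect_equal(r$provenance$rule, "single_exact")

  # single mismatch with unseen identity falls back to the position average
  unseen <- data.frame(position = 4L, sirna_base = "G", target_base = "G")
  r <- lookup_penalty(unseen, tab)
  expect_equal(r$total, mean(c(0.10, 0.30)))
  expect_equal(r$provenance$rule, "position_avg")

  # double with an exact entry, order-independent
  two <- data.frame(position = c(11L, 4L),
                    sirna_base = c("C", "A"), target_base = c("C", "C"))
  r <- lookup_penalty(two, tab)
  expect_equal(r$total, 0.45)
  expect_equal(r$provenance$rule, "double_exact")
  expect_equal(nrow(r$provenance), 1)   # one rule covering both mismatches

  # double without an exact entry: sum of position averages
  two_miss <- data.frame(position = c(1L, 4L),
                         sirna_base = c("A", "G"), target_base = c("A", "G"))
  r <- lookup_penalty(two_miss, tab)
  expect_equal(r$total, 0.066 + 0.20)
  expect_equal(r$provenance$rule, rep("position_avg", 2))

  # three or more mismatches always use position averages, hand-summed
  three <- data.frame(position = c(1L, 4L, 11L),
                      sirna_base = c("U", "A", "C"),
                      target_base = c("G", "C", "C"))
  r <- lookup_penalty(three, tab)
  expect_equal(r$total, 0.066 + 0.20 + 0.50)
  expect_equal(nrow(r$provenance), 3)

  out_of_range <- data.frame(position = 20L, sirna_base = "A",
                             target_base = "A")
  expect_error(lookup_penalty(out_of_range, tab), "1..19")
})

test_that("mismatch efficacy is the predicted efficacy minus the deductions", {
  tab <- fixture_penalty_table()
  mm <- pairing_mismatches(FIG_MUTANT, FIG_TARGET)
  expect_equal(mismatch_efficacy(FIG_E_PRED, mm, tab), FIG_ME)
  expect_equal(mismatch_efficacy(0.5, pairing_mismatches(FIG_ANTISENSE,
                                                         FIG_TARGET), tab),
               0.5)
  # penalties can push ME below zero; it is reported unclipped
  tab2 <- penalty_table(data.frame(position = c(3L, 7L),
                                   sirna_base = c("A", "A"),
                                   target_base = c("A", "A"),
                                   penalty = c(0.2, 0.4)))
  mm2 <- data.frame(position = c(3L, 7L), sirna_base = c("A", "A"),
                    target_base = c("A", "A"))
  expect_equal(mismatch_efficacy(0.5, mm2, tab2), -0.1)
})

test_that("ME never exceeds e_pred under a non-negative penalty table", {
  tab <- generate_synthetic_penalties(seed = 2)
  model <- tiny_model()
  set.seed(37)
  for (i in 1:20) {
    a <- random_rna(19)
    t <- random_rna(19)
    e <- predict_efficacy(model, a)
    me <- mismatch_efficacy(e, pairing_mismatches(a, t), tab)
    expect_lte(me, e + 1e-12)
  }
  # equality iff no mismatches
  t_perfect <- rna_revcomp(FIG_ANTISENSE)
  e <- predict_efficacy(model, FIG_ANTISENSE)
  expect_equal(mismatch_efficacy(e, pairing_mismatches(FIG_ANTISENSE,
                                                       t_perfect), tab), e)
})

test_that("ranking is total, deterministic and collapses to e_pred order
           under a zero penalty table", {
  model <- tiny_model()
  tab <- generate_synthetic_penalties(seed = 2)
  r1 <- rank_mutants(FIG_ANTISENSE, FIG_TARGET, model, tab)
  expect_equal(nrow(r1), 57)
  expect_equal(r1$rank, 1:57)
  expect_true(all(diff(r1$me) <= 0))
  r2 <- rank_mutants(FIG_ANTISENSE, FIG_TARGET, model, tab)
  expect_identical(r1, r2)
  # wild-type entry, when requested, scores ME = e_pred (no mismatches)
  rw <- rank_mutants(FIG_ANTISENSE, FIG_TARGET, model, tab,
                     include_wildtype = TRUE)
  wt <- rw[rw$mutations == "", ]
  expect_equal(nrow(rw), 58)
  expect_equal(wt$me, wt$e_pred)
  expect_equal(wt$n_mismatch, 0L)
  # all-zero penalties make ME == e_pred, so both orders coincide
  zero_tab <- penalty_table(data.frame(position = rep(1:19, each = 12),
                                       sirna_base = rep(mismatch_ids_s, 19),
                                       target_base = rep(mismatch_ids_t, 19),
                                       penalty = 0))
  rz <- rank_mutants(FIG_ANTISENSE, FIG_TARGET, model, zero_tab)
  expect_equal(rz$me, rz$e_pred)
  expect_true(all(diff(rz$e_pred) <= 0))
  # ascending mode reverses the design goal
  ra <- rank_mutants(FIG_ANTISENSE, FIG_TARGET, model, tab, decreasing = FALSE)
  expect_true(all(diff(ra$me) >= 0))
})

test_that("double-depth ranking rescores e_pred per double mutant", {
  model <- tiny_model()
  tab <- generate_synthetic_penalties(seed = 2)
  rd <- rank_mutants(FIG_ANTISENSE, FIG_TARGET, model, tab, depth = "double")
  expect_equal(nrow(rd), 1539)
  expect_true(all(rd$n_mismatch >= 1))
  expect_gte(length(unique(rd$e_pred)), 100)  # re-predicted, not reused
})

test_that("allele discrimination scores both alleles from one e_pred", {
  model <- tiny_model()
  tab <- generate_synthetic_penalties(seed = 2)
  mutant_target <- rna_revcomp(FIG_ANTISENSE)   # fully complementary
  wt_target <- sub("^U", "C", mutant_target)    # SNP at target position 1
  res <- allele_discrimination(FIG_ANTISENSE, mutant_target, wt_target,
                               model, tab)
  expect_equal(nrow(res$mm_mutant), 0)
  expect_equal(res$me_mutant, res$e_pred)
  expect_equal(nrow(res$mm_wt), 1)
  expect_lt(res$me_wt, res$e_pred)
  expect_equal(res$delta, res$me_mutant - res$me_wt)
  expect_gt(res$delta, 0)
  expect_warning(allele_discrimination(FIG_ANTISENSE, mutant_target,
                                       mutant_target, model, tab),
                 "identical")
  # allele-specific design layout: base-substituted siRNA gives 1 mismatch
  # vs the mutant allele and 2 vs wild type
  sub_sirna <- enumerate_single_mutants(FIG_ANTISENSE)$antisense[20]
  res2 <- allele_discrimination(sub_sirna, mutant_target, wt_target,
                                model, tab)
  expect_equal(nrow(res2$mm_mutant), 1)
  expect_equal(nrow(res2$mm_wt), 2)
})
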