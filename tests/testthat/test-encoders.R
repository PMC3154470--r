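test_that("sequence normalization maps DNA to RNA and rejects junk", {
  expect_equal(as_rna("acgt"), "ACGU")
  expect_equal(as_rna(c("AAA", "ttt")), c("AAA", "UUU"))
  expect_error(as_rna("ACGN"), "invalid characters")
  expect_error(as_sirna("ACGU"), "19 or 21")
  expect_equal(rna_revcomp("UCUGAUGUACUUUCCACUG"), "CAGUGGAAAGUACAUCAGA")
})

test_that("k-mer composition matches hand counts and sums to one", {
  expect_equal(unname(kmer_composition("ACGU", 1)), rep(0.25, 4))
  v <- kmer_composition("AAAC", 2)
  expect_equal(v[["AA"]], 2 / 3)
  expect_equal(v[["AC"]], 1 / 3)
  expect_equal(sum(v), 1)
  expect_error(kmer_composition("ACGU", 5), "1..4")
  expect_error(kmer_composition("AC", 3), "shorter")
  # lexicographic ordering with leftmost position most significant
  expect_equal(names(kmer_composition("ACGU", 2))[1:5],
               c("AA", "AC", "AG", "AU", "CA"))
})

test_that("composition encoders agree with a naive nested-loop oracle", {
  set.seed(42)
  for (i in 1:30) {
    s <- random_rna(21)
    for (k in 1:4) {
      expect_equal(kmer_composition(s, k), naive_tuple_composition(s, k),
                   tolerance = 1e-12)
    }
    expect_equal(gapped_composition(s, 2, 2),
                 naive_tuple_composition(s, 2, order = 2), tolerance = 1e-12)
    expect_equal(gapped_composition(s, 3, 2),
                 naive_tuple_composition(s, 3, order = 2), tolerance = 1e-12)
    expect_equal(gapped_composition(s, 2, 4),
                 naive_tuple_composition(s, 2, order = 4), tolerance = 1e-12)
  }
})

test_that("split composition shares the middle base of odd-length input", {
  v <- split_composition(strrep("A", 21), 1)
  expect_length(v, 8)
  expect_equal(v[["h1.A"]], 1)
  expect_equal(v[["h2.A"]], 1)
  # a 21-mer splits into first 11 nt and last 11 nt
  s <- paste0(strrep("A", 11), strrep("G", 10))
  v <- split_composition(s, 1)
  expect_equal(v[["h1.A"]], 1)                 # positions 1..11 all A
  expect_equal(v[["h2.A"]], 1 / 11)            # position 11 is the shared A
  expect_equal(v[["h2.G"]], 10 / 11)
  expect_length(split_composition(random_rna(21), 2), 32)
  expect_length(split_composition(random_rna(21), 3), 128)
  # even length splits exactly in half
  v <- split_composition("AAGG", 1)
  expect_equal(v[["h1.A"]], 1)
  expect_equal(v[["h2.G"]], 1)
})

test_that("gapped composition handles its documented examples", {
  v <- gapped_composition("ACGU", 2, 2)
  expect_equal(v[["AG"]], 0.5)
  expect_equal(v[["CU"]], 0.5)
  expect_equal(sum(v), 1)
  expect_equal(gapped_composition("AAAA", 2, 3)[["AA"]], 1)
  expect_error(gapped_composition("ACG", 2, 3), "span")
})

test_that("positional one-hot encoders have one 1 per block", {
  expect_equal(unname(binary_pattern("A")), c(1, 0, 0, 0))
  set.seed(7)
  for (i in 1:20) {
    s <- random_rna(21)
    bp <- binary_pattern(s)
    blocks <- matrix(bp, nrow = 4)
    expect_true(all(colSums(blocks) == 1))
    bd <- binary_dinucleotide(s)
    expect_true(all(colSums(matrix(bd, nrow = 16)) == 1))
  }
  v <- binary_dinucleotide("AC")
  expect_equal(sum(v), 1)
  expect_equal(v[["pos01.AC"]], 1)
  expect_error(binary_dinucleotide("A"), ">= 2")
})

test_that("condensed encoding merges mirrored positions and drops the middle", {
  expect_equal(unname(condensed_binary("AU")), c(1, 0, 0, 1))
  v <- condensed_binary("AAUU")
  expect_equal(unname(v), c(1, 0, 0, 1, 1, 0, 0, 1))
  expect_length(condensed_binary(random_rna(21)), 40)
  # middle base of an odd-length sequence does not contribute
  expect_equal(unname(condensed_binary("AGA")), c(2, 0, 0, 0))
})

test_that("AU/GC and hydrogen-bond encoders follow the base-class rules", {
  expect_equal(unname(au_gc_pattern("G")), c(0, 1))
  expect_equal(unname(au_gc_pattern("AG")), c(1, 0, 0, 1))
  expect_equal(unname(hydrogen_bond("GCAU")), c(3, 3, 2, 2))
  expect_equal(unname(hydrogen_bond("AAAA")), rep(2, 4))
})

test_that("thermodynamic profile reads the nearest-neighbor table", {
  zero_tab <- setNames(rep(0, 16), names(default_nn_table()))
  expect_equal(unname(thermo_profile(random_rna(21), zero_tab)), rep(0, 19))
  expect_equal(unname(thermo_profile(strrep("A", 21))), rep(-0.93, 19))
  expect_error(thermo_profile(strrep("A", 21), c(AA = -0.93)), "missing")
  expect_error(thermo_profile(random_rna(19)), ">= 20")
  tab <- default_nn_table()
  expect_length(tab, 16)
  expect_true(all(tab < 0))
})

test_that("encoder dimensions match the published vector sizes on 21-mers", {
  s <- random_rna(21)
  dims <- c(mono = 4, di = 16, tri = 64, tetra = 256,
            split_mono = 8, split_di = 32, split_tri = 128,
            gapped_di_2 = 16, binary = 84, binary_di = 320,
            condensed = 40, au_gc = 42, hbond = 21, thermo = 19)
  for (nm in names(dims)) {
    spec <- encoding_spec(nm)
    expect_length(build_hybrid(s, spec), dims[[nm]])
  }
  expect_length(build_hybrid(s, encoding_spec()), 168)          # 4+16+64+84
  expect_length(build_hybrid(random_rna(19), encoding_spec()), 160)
})

test_that("hybrid assembly appends accessibility and propagates errors", {
  s <- random_rna(19)
  spec <- encoding_spec(c("mono", "di", "tri", "binary", "accessibility"))
  v <- build_hybrid(s, spec, accessibility = 0.42)
  expect_length(v, 161)
  expect_equal(v[["accessibility.value"]], 0.42)
  expect_error(build_hybrid(s, spec), "accessibility")
  expect_error(encoding_spec("nonsense"), "unknown encoder")
  # component failure is attributed to the encoder that raised it
  expect_error(build_hybrid("ACG", encoding_spec(c("mono", "tetra"))),
               "encoder 'tetra'")
})

test_that("min-max scaling maps train range to [low, high] without clipping", {
  m <- matrix(c(0, 5, 10), ncol = 1, dimnames = list(NULL, "f"))
  p <- fit_scaler(m, 1, 10)
  expect_equal(as.numeric(apply_scaler(m, p)), c(1, 5.5, 10))
  const <- matrix(c(3, 3, 3), ncol = 1, dimnames = list(NULL, "f"))
  expect_equal(as.numeric(apply_scaler(const, fit_scaler(const))), c(1, 1, 1))
  # held-out values beyond the training range extrapolate linearly
  tr <- matrix(c(2, 4), ncol = 1, dimnames = list(NULL, "f"))
  p <- fit_scaler(tr, 1, 10)
  expect_equal(as.numeric(apply_scaler(matrix(6, 1, 1,
                                              dimnames = list(NULL, "f")), p)),
               19)
  expect_error(fit_scaler(matrix(numeric(0), 0, 1)), "non-empty")
  expect_error(apply_scaler(matrix(1, 1, 2, dimnames = list(NULL, c("a", "b"))),
                            p), "columns")
})

test_that("scaling is idempotent on scaled data and order-preserving", {
  set.seed(11)
  m <- encode_features(replicate(30, random_rna(21)), encoding_spec())
  p <- fit_scaler(m)
  ms <- apply_scaler(m, p)
  expect_true(all(ms >= 1 - 1e-12 & ms <= 10 + 1e-12))
  p2 <- fit_scaler(ms)
  expect_equal(apply_scaler(ms, p2), ms, tolerance = 1e-12)
  for (j in sample(ncol(m), 10)) {
    expect_equal(order(m[, j]), order(ms[, j]))
  }
})
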