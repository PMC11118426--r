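test_that("single-position embeddings match their definitions", {
  abc <- c("A", "B", "C")
  expect_equal(onehot_single("A", abc), c(1L, 0L, 0L))
  expect_equal(onehot_single("C", abc), c(0L, 0L, 1L))
  expect_error(onehot_single("X", abc), "unknown")
  # indicator completeness: sum over characters is all-ones
  expect_equal(Reduce(`+`, lapply(abc, onehot_single, alphabet = abc)),
               rep(1L, 3))

  expect_equal(simplex_single("A", abc), c(1L, 0L))
  expect_equal(simplex_single("B", abc), c(0L, 1L))
  expect_equal(simplex_single("C", abc), c(-1L, -1L))
  # zero-centered: sum over characters vanishes
  for (a in 2:4) {
    alph <- c("A", "B", "C", "D")[seq_len(a)]
    expect_equal(Reduce(`+`, lapply(alph, simplex_single, alphabet = alph)),
                 rep(0L, a - 1))
  }
})

test_that("sequence embedding: pairwise one-hot has the indicator structure", {
  m <- sfr_preset("pairwise", "AB", 2)
  expect_equal(m$M, 9)
  x <- embed_sequence(m, "AB")
  expect_true(all(x %in% c(0, 1)))
  expect_equal(names(x)[x == 1],
               c("theta_0", "theta_1:A", "theta_2:B", "theta_1,2:AB"))
})

test_that("all-order one-hot embeddings have one 1 per subset block", {
  m <- sfr_preset("all-order", "ABC", 3)
  expect_equal(m$M, 64)
  for (s in c("ABC", "CAB", "BBB")) {
    x <- embed_sequence(m, s)
    expect_equal(sum(x), 8)  # 2^3 subset blocks, each an indicator
    expect_true(all(x %in% c(0, 1)))
  }
})

test_that("constant and degenerate models embed correctly", {
  m <- sfr_model("AB", 2, "one-hot", list(integer(0)))
  for (s in enumerate_sequences(c("A", "B"), 2)) {
    expect_equal(unname(embed_sequence(m, s)), 1)
  }
  m0 <- sfr_model("AB", 2, "simplex", list())
  expect_equal(m0$M, 0)
  expect_length(embed_sequence(m0, "AB"), 0)
})

test_that("design matrices have the expected ranks", {
  # pairwise one-hot at alpha=2, L=2: 4 x 9 binary, rank 1+(a-1)L+C(L,2)(a-1)^2
  m <- sfr_preset("pairwise", "AB", 2)
  X <- design_matrix(m)
  expect_equal(dim(X), c(4L, 9L))
  expect_true(all(X %in% c(0, 1)))
  expect_equal(qr(X)$rank, 4)
  # matched simplex model: 4 x 4, full rank
  ms <- sfr_preset("pairwise", "AB", 2, flavor = "simplex")
  Xs <- design_matrix(ms)
  expect_equal(dim(Xs), c(4L, 4L))
  expect_equal(qr(Xs)$rank, 4)
  # constant model: the all-ones column
  expect_equal(unname(design_matrix(sfr_preset("constant", "ABC", 2))),
               matrix(1, 9, 1))
})

test_that("embedding entries respect the flavor value sets", {
  for (flavor in c("one-hot", "simplex")) {
    m <- sfr_preset("pairwise", "ABC", 3, flavor = flavor)
    X <- design_matrix(m)
    if (flavor == "one-hot") expect_true(all(X %in% c(0, 1)))
    else expect_true(all(X %in% c(-1, 0, 1)))
  }
})

test_that("model evaluation is the inner product with the embedding", {
  m <- sfr_preset("pairwise", "AB", 2)
  seqs <- enumerate_sequences(c("A", "B"), 2)
  expect_equal(unname(evaluate_model(m, rep(0, m$M), seqs)), rep(0, 4))
  mc <- sfr_preset("constant", "AB", 2)
  expect_equal(unname(evaluate_model(mc, 2.5, seqs)), rep(2.5, 4))
  # indicator parameter picks out exactly its sequence
  theta <- as.numeric(m$labels == "theta_1,2:AB")
  expect_equal(unname(evaluate_model(m, theta, seqs)),
               as.numeric(seqs == "AB"))
  # named parameters may arrive in any order
  theta2 <- stats::setNames(seq_len(m$M), m$labels)
  shuffled <- theta2[sample(m$M)]
  expect_equal(evaluate_model(m, shuffled, seqs),
               evaluate_model(m, theta2, seqs))
})

test_that("presets produce the documented set counts and sizes", {
  m <- sfr_preset("pairwise", "ACGT", 5)
  expect_length(m$sets, 1 + 5 + choose(5, 2))
  m <- sfr_preset("all-order", "ABC", 3)
  expect_length(m$sets, 8)
  expect_equal(m$M, 64)
  m <- sfr_preset("nearest-neighbor", "ABC", 4)
  expect_equal(count_params(m), 1 + 4 * 3 + 3 * 9)
  m <- sfr_preset("K-adjacent", "AB", 4, K = 2)
  expect_equal(lapply(m$sets, as.integer),
               list(1:2, 2:3, 3:4))
  expect_error(sfr_preset("K-order", "AB", 3), "requires K")
  expect_error(sfr_preset("K-order", "AB", 3, K = 5), "K must be")
  expect_error(sfr_preset("ridge", "AB", 3), "unknown preset")
})

test_that("duplicate position sets are allowed and labelled uniquely", {
  m <- sfr_model("ABC", 2, "one-hot", list(integer(0), 1L, 1L))
  expect_equal(m$M, 7)
  expect_false(anyDuplicated(m$labels) > 0)
  expect_true("theta_1:A#2" %in% m$labels)
  # both copies embed identically
  x <- embed_sequence(m, "BA")
  expect_equal(unname(x[2:4]), unname(x[5:7]))
})

test_that("parameter counting stays combinatorial at large L", {
  m <- sfr_model("ACGT", 1000, "one-hot",
                 c(list(integer(0)), lapply(seq_len(1000), identity)))
  expect_equal(count_params(m), 1 + 1000 * 4)
  # closed form survives sizes where no matrix could be built
  mk <- sfr_preset("K-adjacent", "ACGT", 500, K = 3)
  expect_equal(count_params(mk), (500 - 3 + 1) * 4^3)
})

test_that("one-hot and simplex design matrices span the same space", {
  for (cfg in list(c(2, 2), c(3, 2), c(3, 3), c(2, 3))) {
    a <- cfg[1]; L <- cfg[2]
    alph <- c("A", "B", "C")[seq_len(a)]
    mo <- sfr_preset("pairwise", alph, L)
    ms <- sfr_preset("pairwise", alph, L, flavor = "simplex")
    expect_true(span_equal(mo, ms))
  }
})
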