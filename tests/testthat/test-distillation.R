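test_that("similarity transformation matches the closed form", {
  T3 <- similarity_T(3)
  expect_equal(T3$T, rbind(c(1L, 1L, 1L), c(1L, 0L, -1L), c(0L, 1L, -1L)))
  expect_equal(similarity_T(2)$T, rbind(c(1L, 1L), c(1L, -1L)))
  # T maps one-hot onto trivial + simplex for every character and alpha
  for (a in 2:5) {
    alph <- c("A", "B", "C", "D", "E")[seq_len(a)]
    Tm <- similarity_T(a)
    expect_dense_equal(Tm$T %*% Tm$Tinv, diag(a))
    for (c in alph) {
      expect_equal(as.numeric(Tm$T %*% onehot_single(c, alph)),
                   c(1, simplex_single(c, alph)))
    }
  }
  # worked instance: T (0,0,1) = (1,-1,-1)
  expect_equal(as.numeric(T3$T %*% c(0, 0, 1)), c(1, -1, -1))
})

test_that("Tdecom groups coordinates into simplex sub-blocks", {
  # constant model: 1x1 identity
  dec <- build_Tdecom(sfr_preset("constant", "ABC", 2))
  expect_equal(as.matrix(dec$Tdecom), matrix(1, 1, 1))
  # single-position block: T itself with sub-blocks {} (dim 1), {l} (dim a-1)
  m1 <- sfr_model("ABC", 2, "one-hot", list(1L))
  dec1 <- build_Tdecom(m1)
  expect_equal(unname(as.matrix(dec1$Tdecom)),
               matrix(as.numeric(similarity_T(3)$T), 3))
  expect_equal(dec1$blocks$dim, c(1, 2))
  expect_equal(dec1$blocks$key, c("", "1"))
  # pairwise: multiplicities Q_{} = 1+L+C(L,2), Q_{l} = L, Q_{ll'} = 1
  m <- sfr_preset("pairwise", "ABC", 3)
  dec <- build_Tdecom(m)
  expect_equal(sum(dec$blocks$key == ""), 1 + 3 + choose(3, 2))
  for (l in 1:3) {
    expect_equal(sum(dec$blocks$key == as.character(l)), 3)
  }
  expect_equal(sum(dec$blocks$key == "1,2"), 1)
})

test_that("thinning zeroes every redundant copy on all embeddings", {
  m <- sfr_preset("additive", "ABC", 3)
  dec <- build_Tdecom(m)
  thin <- build_Tthin(dec$blocks, m$M)
  expect_dense_equal(thin$Tthin %*% thin$Tthin_inv, diag(m$M))
  X <- design_matrix(m)
  Z <- as.matrix(thin$Tthin %*% dec$Tdecom %*% t(X))
  # the L+1 copies of the trivial sub-block reduce to one kept copy
  first <- !duplicated(dec$blocks$key)
  for (r in which(!first)) {
    rows <- dec$blocks$start[r] + seq_len(dec$blocks$dim[r]) - 1
    expect_equal(max(abs(Z[rows, ])), 0)
  }
  # no redundancy -> Tthin is the identity
  ms <- sfr_preset("pairwise", "ABC", 2, flavor = "simplex")
  decs <- build_Tdecom(ms)
  thins <- build_Tthin(decs$blocks, ms$M)
  expect_dense_equal(thins$Tthin, diag(ms$M))
})

test_that("sorting is an orthogonal permutation", {
  m <- sfr_preset("all-order", "ABC", 3)
  dec <- build_Tdecom(m)
  P <- build_Tsort(dec$blocks, m$M)
  expect_true(all(P@x == 1))
  expect_equal(Matrix::nnzero(P), m$M)
  expect_dense_equal(Matrix::t(P) %*% P, diag(m$M))
})

test_that("distillation certificate holds exactly across the model suite", {
  for (m in small_model_suite()) {
    d <- distill(m)
    M <- m$M
    g <- d$gamma
    X <- design_matrix(m)
    Z <- as.matrix(Matrix::tcrossprod(d$Tdist, X))
    # last gamma coordinates vanish for every sequence
    if (g > 0) {
      expect_equal(max(abs(Z[M - g + seq_len(g), , drop = FALSE])), 0)
    }
    # top block equals the simplex embedding over the distinct subsets
    D <- design_matrix(d$distilled_model)
    expect_equal(unname(t(Z[seq_len(M - g), , drop = FALSE])), unname(D))
    # entries of Tdist are +/-1; inverse is exact
    expect_true(all(abs(d$Tdist@x) == 1))
    expect_dense_equal(d$Tdist %*% d$Tdist_inv, diag(M))
    # gamma agrees with both analytic formulas and the block bookkeeping
    detail <- seqgauge:::gauge_count_detail(m)
    expect_equal(g, detail$gamma_by_difference)
    expect_equal(g, detail$gamma_by_multiplicity)
    expect_equal(g, M - sum((m$alpha - 1)^lengths(d$subsets)))
  }
})

test_that("the distilled representation is block-diagonal (distilled + redundant)", {
  for (m in list(sfr_preset("pairwise", "ABC", 2),
                 sfr_preset("additive", "AB", 3))) {
    d <- distill(m)
    M <- m$M
    g <- d$gamma
    top <- seq_len(M - g)
    bottom <- M - g + seq_len(g)
    for (seed in 1:5) {
      h <- random_pscp(m$alphabet, m$L, seed = seed)
      C <- as.matrix(d$Tdist %*% model_rep(m, h) %*% d$Tdist_inv)
      expect_lt(max(abs(C[top, bottom])), 1e-9)
      expect_lt(max(abs(C[bottom, top])), 1e-9)
      # distilled block acts as the representation of the distilled model
      Rd <- as.matrix(model_rep(d$distilled_model, h))
      expect_dense_equal(C[top, top, drop = FALSE], Rd)
    }
  }
})

test_that("pairwise one-hot distills to the pairwise simplex embedding", {
  m <- sfr_preset("pairwise", "ABC", 2)
  d <- distill(m)
  ms <- sfr_preset("pairwise", "ABC", 2, flavor = "simplex")
  expect_equal(lapply(d$distilled_model$sets, as.integer),
               lapply(ms$sets, as.integer))
  expect_equal(d$distilled_labels, ms$labels)
  expect_equal(d$gamma, m$M - ms$M)
})

test_that("distillation handles constant and duplicate-set models", {
  d0 <- distill(sfr_preset("constant", "ABC", 2))
  expect_equal(as.matrix(d0$Tdist), matrix(1, 1, 1))
  expect_equal(d0$gamma, 0)
  # duplicated additive block: the duplicate contributes alpha extra freedoms
  mdup <- sfr_model("ABC", 2, "one-hot", list(integer(0), 1L, 1L))
  ddup <- distill(mdup)
  expect_equal(ddup$gamma, mdup$M - (1 + 2))
  expect_true(is_gauge_vector(mdup, as.numeric(gauge_basis(ddup)[1, ])))
})

test_that("analytic counts match Table-style closed forms and the oracle", {
  for (cs in preset_grid()) {
    m <- sfr_preset(cs$name, cs$alphabet, cs$L, K = cs$K)
    expect_equal(count_params(m), closed_form_M(cs$name, cs$a, cs$L, cs$K),
                 info = paste(cs$name, cs$a, cs$L))
    expect_equal(count_gauge(m),
                 closed_form_gamma(cs$name, cs$a, cs$L, cs$K),
                 info = paste(cs$name, cs$a, cs$L))
    expect_equal(count_gauge(m), nullspace_dim(m),
                 info = paste(cs$name, cs$a, cs$L))
  }
  # any one-hot spec with J = 1 has no gauge freedoms; J >= 2 has >= J - 1
  expect_equal(count_gauge(sfr_model("ABC", 3, "one-hot", list(c(1L, 3L)))),
               0)
  set.seed(11)
  for (rep in 1:10) {
    J <- sample(2:5, 1)
    sets <- unique(lapply(seq_len(J), function(i)
      sort(sample(3L, sample(0:3, 1)))))
    m <- sfr_model("ABC", 3, "one-hot", sets)
    if (length(sets) >= 2) {
      expect_gte(count_gauge(m), length(sets) - 1)
    }
  }
})

test_that("counting scales combinatorially without building matrices", {
  m <- sfr_preset("pairwise", "ACGT", 200)
  expect_equal(count_gauge(m), 200 + choose(200, 2) * (2 * 4 - 1))
  expect_equal(count_params(m), 1 + 200 * 4 + choose(200, 2) * 16)
})

test_that("Tdist nonzeros grow quadratically for pairwise models", {
  nnz <- vapply(c(4, 8, 16), function(L) {
    Matrix::nnzero(distill(sfr_preset("pairwise", "ACGT", L))$Tdist)
  }, numeric(1))
  # quadratic feature count => nonzeros bounded by a constant times L^2
  ratio <- nnz / c(4, 8, 16)^2
  expect_lt(max(ratio) / min(ratio), 3)
})

test_that("equivariance classes enumerate as 2^(2^L) distilled models", {
  cls1 <- enumerate_model_classes(1)
  expect_length(cls1, 4)
  cls2 <- enumerate_model_classes(2)
  expect_length(cls2, 16)
  # classes are distinct as subset families and all gauge-free
  keys <- vapply(cls2, function(m)
    paste(vapply(m$sets, function(B)
      paste0("{", paste(B, collapse = ","), "}"), character(1)),
      collapse = ";"), character(1))
  expect_false(anyDuplicated(keys) > 0)
  for (m in cls2) expect_equal(count_gauge(m), 0)
  expect_error(enumerate_model_classes(5), "too large")
})
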