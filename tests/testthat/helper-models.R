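# Shared fixtures: closed-form parameter/gauge counts for the standard
# model families, and the small-model suite used across tests.

# closed forms for M (number of parameters), one-hot flavor
closed_form_M <- function(name, a, L, K = NULL) {
  switch(name,
    "constant" = 1,
    "additive" = 1 + L * a,
    "pairwise" = 1 + L * a + choose(L, 2) * a^2,
    "nearest-neighbor" = 1 + L * a + (L - 1) * a^2,
    "all-order" = (a + 1)^L,
    "all-adjacent" = 1 + a / (a - 1)^2 * (a^(L + 1) - (L + 1) * a + L),
    "K-order" = choose(L, K) * a^K,
    "hierarchical-K-order" = sum(choose(L, 0:K) * a^(0:K)),
    "K-adjacent" = (L - K + 1) * a^K,
    "hierarchical-K-adjacent" =
      1 + sum((L - seq_len(K) + 1) * a^seq_len(K)),
    stop("unknown: ", name))
}

# closed forms for gamma (number of gauge freedoms), one-hot flavor
closed_form_gamma <- function(name, a, L, K = NULL) {
  switch(name,
    "constant" = 0,
    "additive" = L,
    "pairwise" = L + choose(L, 2) * (2 * a - 1),
    "nearest-neighbor" = L + (L - 1) * (2 * a - 1),
    "all-order" = (a + 1)^L - a^L,
    "all-adjacent" =
      1 + a / (a - 1)^2 * (2 * a^L - a^(L - 1) - (L + 1) * a + L),
    "K-order" = choose(L, K) * a^K - sum(choose(L, 0:K) * (a - 1)^(0:K)),
    "hierarchical-K-order" =
      sum(choose(L, 0:K) * (a^(0:K) - (a - 1)^(0:K))),
    "K-adjacent" = (L - K) * a^(K - 1),
    "hierarchical-K-adjacent" =
      (L - K) * a^(K - 1) + 1 +
        (if (K >= 2) sum((L - seq_len(K - 1) + 1) * a^seq_len(K - 1))
         else 0),
    stop("unknown: ", name))
}

preset_names <- c("constant", "additive", "pairwise", "nearest-neighbor",
                  "all-order", "all-adjacent", "K-order",
                  "hierarchical-K-order", "K-adjacent",
                  "hierarchical-K-adjacent")

needs_K <- function(name) grepl("K", name, fixed = TRUE)

# every preset at every (alpha, L) in {2,3,4} x {2,3}, K over 1..L
preset_grid <- function(alphas = 2:4, Ls = 2:3) {
  out <- list()
  full <- c("A", "B", "C", "D")
  for (a in alphas) for (L in Ls) for (name in preset_names) {
    Ks <- if (needs_K(name)) seq_len(L) else NA
    for (K in Ks) {
      out[[length(out) + 1L]] <- list(
        name = name, alphabet = full[seq_len(a)], a = a, L = L,
        K = if (is.na(K)) NULL else K)
    }
  }
  out
}

# compact suite of small models exercised by exhaustive certificates
small_model_suite <- function() {
  list(
    sfr_preset("constant", "AB", 2),
    sfr_preset("additive", "AB", 3),
    sfr_preset("pairwise", "AB", 2),
    sfr_preset("pairwise", "ABC", 2),
    sfr_preset("pairwise", "ABCD", 3),
    sfr_preset("nearest-neighbor", "ABC", 3),
    sfr_preset("all-order", "ABC", 3),
    sfr_preset("all-adjacent", "AB", 3),
    sfr_preset("K-order", "ABC", 3, K = 2),
    sfr_preset("hierarchical-K-adjacent", "ABC", 3, K = 2),
    # duplicated position sets are legal and produce extra redundancy
    sfr_model("ABC", 2, "one-hot", list(integer(0), 1L, 1L, c(1L, 2L)))
  )
}

expect_dense_equal <- function(x, y, tol = 1e-9) {
  expect_lte(max(abs(as.matrix(x) - as.matrix(y))), tol)
}
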