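#' Single-position Maschke similarity transformation
#'
#' The `alpha x alpha` matrix `T` that maps the one-hot embedding of every
#' character onto the direct sum of the trivial embedding and the simplex
#' embedding: `T %*% onehot_single(c) == c(1, simplex_single(c))`. Its first
#' row is all ones; row `i + 1` has a 1 in column `i` and a -1 in the last
#' column. The inverse is returned in closed form (entries are integer
#' multiples of `1/alpha`).
#'
#' @param alpha Alphabet size (integer, at least 2).
#' @return List with integer matrix `T` and numeric matrix `Tinv`.
#' @examples
#' similarity_T(3)$T  # rbind(c(1,1,1), c(1,0,-1), c(0,1,-1))
#' @export
similarity_T <- function(alpha) {
  alpha <- as.integer(alpha)
  stopifnot(alpha >= 2L)
  Tm <- matrix(0L, alpha, alpha)
  Tm[1L, ] <- 1L
  for (i in seq_len(alpha - 1L)) {
    Tm[i + 1L, i] <- 1L
    Tm[i + 1L, alpha] <- -1L
  }
  # closed-form inverse: x_i = (y_0 - sum_j y_j)/alpha + y_i (i < alpha),
  # x_alpha = (y_0 - sum_j y_j)/alpha, where y = T x = (sum; differences)
  Ti <- matrix(-1, alpha, alpha)
  Ti[, 1L] <- 1
  for (i in seq_len(alpha - 1L)) Ti[i, i + 1L] <- alpha - 1
  Ti <- Ti / alpha
  list(T = Tm, Tinv = Ti)
}

subset_key <- function(B) paste(B, collapse = ",")

# canonical order for subsets: cardinality ascending, then lexicographic
# on the (sorted) position vectors
subset_order <- function(subsets) {
  sizes <- lengths(subsets)
  lex <- vapply(subsets, function(B)
    paste(sprintf("%05d", B), collapse = ","), character(1))
  order(sizes, lex)
}

#' Maschke decomposition matrix for a model
#'
#' Builds the block-diagonal similarity transformation `Tdecom` that maps
#' each one-hot Kronecker block onto a direct sum of simplex Kronecker
#' sub-blocks, one for every subset `B` of the block's position set `A_j`.
#' Within each block the Kronecker product of single-position `T` factors
#' interleaves trivial and simplex components; a fixed permutation regroups
#' the coordinates so each sub-block is contiguous, ordered by `|B|`
#' ascending then lexicographically. Simplex-flavor models are already
#' decomposed, so `Tdecom` is the identity and each block is its own
#' sub-block.
#'
#' @param model An `"sfr_model"`.
#' @return List with sparse matrices `Tdecom` and `Tdecom_inv`, and
#'   `blocks`: a data frame with one row per sub-block (`j`, `key`, `size`,
#'   `dim`, `start` = 1-based offset of the sub-block in the transformed
#'   embedding).
#' @export
build_Tdecom <- function(model) {
  stopifnot(inherits(model, "sfr_model"))
  a <- model$alpha
  M <- model$M
  if (model$flavor == "simplex" || length(model$sets) == 0L) {
    blocks <- data.frame(
      j = seq_along(model$sets),
      key = vapply(model$sets, subset_key, character(1)),
      size = lengths(model$sets),
      dim = model$block_dim,
      start = model$block_offset + 1,
      stringsAsFactors = FALSE)
    I <- Matrix::Diagonal(M)
    return(list(Tdecom = methods::as(I, "CsparseMatrix"),
                Tdecom_inv = methods::as(I, "CsparseMatrix"),
                blocks = blocks))
  }
  Tm <- similarity_T(a)
  Tsp <- methods::as(Matrix::Matrix(Tm$T, sparse = TRUE), "CsparseMatrix")
  Tisp <- methods::as(Matrix::Matrix(Tm$Tinv, sparse = TRUE),
                      "CsparseMatrix")
  one <- Matrix::Diagonal(1)
  blk <- vector("list", length(model$sets))
  blk_inv <- vector("list", length(model$sets))
  rows <- vector("list", length(model$sets))
  for (j in seq_along(model$sets)) {
    A <- model$sets[[j]]
    m <- length(A)
    K <- Reduce(`%x%`, rep(list(Tsp), m), one)
    Kinv <- Reduce(`%x%`, rep(list(Tisp), m), one)
    if (m == 0L) {
      blk[[j]] <- one
      blk_inv[[j]] <- one
      rows[[j]] <- data.frame(j = j, key = "", size = 0L, dim = 1,
                              stringsAsFactors = FALSE)
      next
    }
    # coordinate (i_1, ..., i_m), i_t in 1..alpha, first factor slowest;
    # i_t == 1 is the trivial component of factor t, i_t > 1 its simplex
    # component; the subset B collects positions with a simplex component
    tuples <- char_tuples(seq_len(a), m)
    subs <- lapply(seq_len(nrow(tuples)), function(r)
      A[tuples[r, ] > 1L])
    ord <- subset_order(subs)  # stable: preserves simplex kron order in B
    blk[[j]] <- K[ord, , drop = FALSE]
    blk_inv[[j]] <- Kinv[, ord, drop = FALSE]
    sorted <- subs[ord]
    keys <- vapply(sorted, subset_key, character(1))
    run <- rle(keys)
    rows[[j]] <- data.frame(
      j = j, key = run$values,
      size = lengths(sorted[cumsum(run$lengths)]),
      dim = run$lengths, stringsAsFactors = FALSE)
  }
  blocks <- do.call(rbind, rows)
  blocks$start <- cumsum(c(1, blocks$dim))[seq_len(nrow(blocks))]
  # each sub-block must have the simplex dimension (alpha-1)^|B|
  stopifnot(all(blocks$dim == (a - 1)^blocks$size))
  list(Tdecom = methods::as(Matrix::bdiag(blk), "CsparseMatrix"),
       Tdecom_inv = methods::as(Matrix::bdiag(blk_inv), "CsparseMatrix"),
       blocks = blocks)
}

#' Thinning transformation
#'
#' Identity except that each non-first copy of a repeated irreducible
#' sub-block is replaced by (that copy) minus (the first, kept copy). After
#' `Tdecom`, repeated copies of the same subset's simplex embedding are
#' equal coordinate-by-coordinate, so thinning zeroes every redundant copy
#' on all sequence embeddings. Entries are in `{-1, 0, +1}`; the inverse
#' re-adds the kept copy (`+1` in place of `-1`).
#'
#' @param blocks Sub-block table from [build_Tdecom()].
#' @param M Embedding dimension.
#' @return List with sparse `Tthin` and `Tthin_inv`.
#' @export
build_Tthin <- function(blocks, M) {
  first <- !duplicated(blocks$key)
  kept_start <- stats::setNames(blocks$start[first],
                                paste0("k", blocks$key[first]))
  ii <- integer(0); jj <- integer(0)
  for (r in which(!first)) {
    d <- blocks$dim[r]
    ii <- c(ii, blocks$start[r] + seq_len(d) - 1L)
    jj <- c(jj, kept_start[[paste0("k", blocks$key[r])]] + seq_len(d) - 1L)
  }
  I <- Matrix::Diagonal(M)
  if (length(ii) == 0L) {
    I <- methods::as(I, "CsparseMatrix")
    return(list(Tthin = I, Tthin_inv = I))
  }
  N <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(M, M))
  list(Tthin = methods::as(I - N, "CsparseMatrix"),
       Tthin_inv = methods::as(I + N, "CsparseMatrix"))
}

#' Sorting permutation
#'
#' Permutation matrix that moves the kept (first-copy) sub-blocks to the
#' top, ordered by subset cardinality then lexicographically by positions,
#' and stacks the zeroed redundant coordinates below them in scan order.
#'
#' @inheritParams build_Tthin
#' @return Sparse permutation matrix `Tsort` (orthogonal:
#'   `t(Tsort) %*% Tsort` is the identity).
#' @export
build_Tsort <- function(blocks, M) {
  first <- !duplicated(blocks$key)
  kept <- blocks[first, , drop = FALSE]
  ksub <- lapply(strsplit(kept$key, ","), as.integer)
  kept <- kept[subset_order(ksub), , drop = FALSE]
  redundant <- blocks[!first, , drop = FALSE]
  old <- c(unlist(lapply(seq_len(nrow(kept)), function(r)
             kept$start[r] + seq_len(kept$dim[r]) - 1L)),
           unlist(lapply(seq_len(nrow(redundant)), function(r)
             redundant$start[r] + seq_len(redundant$dim[r]) - 1L)))
  if (M == 0L) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                x = numeric(0), dims = c(0L, 0L)))
  }
  Matrix::sparseMatrix(i = seq_len(M), j = old, x = 1, dims = c(M, M))
}

#' Distill a model's embedding
#'
#' Runs the full embedding-distillation procedure
#' `Tdist = Tsort %*% Tthin %*% Tdecom`. For every sequence `s`,
#' `Tdist %*% embed_sequence(model, s)` equals the simplex embedding over
#' the distinct position subsets `B_k` (the distilled embedding) stacked on
#' a `gamma`-dimensional zero vector; `gamma` is the number of gauge
#' freedoms of the model. Every nonzero entry of `Tdist` is +1 or -1, so
#' its last `gamma` rows are a sparse signed basis of the gauge space.
#'
#' @param model An `"sfr_model"` (either flavor; simplex blocks are already
#'   irreducible and only thinning/sorting apply).
#' @param verify If `TRUE`, exhaustively certifies the zero block over all
#'   `alpha^L` sequences (requires `alpha^L <= cap`).
#' @param cap Enumeration cap used when `verify = TRUE`.
#' @return An object of class `"sfr_distillation"`: `Tdist`, `Tdist_inv`,
#'   `gamma`, `M`, `subsets` (distinct `B_k`, canonical order),
#'   `multiplicity` (`Q_k`), `distilled_model` (simplex-flavor
#'   `"sfr_model"` over the `B_k`), `distilled_labels`, `blocks`, `model`.
#' @examples
#' d <- distill(sfr_preset("pairwise", "AB", 2))
#' d$gamma  # 5
#' @export
distill <- function(model, verify = FALSE, cap = 1e6) {
  stopifnot(inherits(model, "sfr_model"))
  M <- model$M
  dec <- build_Tdecom(model)
  thin <- build_Tthin(dec$blocks, M)
  Tsort <- build_Tsort(dec$blocks, M)
  Tdist <- Matrix::drop0(Tsort %*% thin$Tthin %*% dec$Tdecom)
  Tinv <- Matrix::drop0(dec$Tdecom_inv %*% thin$Tthin_inv %*%
                          Matrix::t(Tsort))
  first <- !duplicated(dec$blocks$key)
  subs <- lapply(strsplit(dec$blocks$key[first], ","), as.integer)
  subs <- subs[subset_order(subs)]
  Q <- table(paste0("k", dec$blocks$key))
  Q <- as.integer(Q[paste0("k", vapply(subs, subset_key, character(1)))])
  distilled <- sfr_model(model$alphabet, model$L, "simplex", subs)
  gamma <- M - distilled$M
  res <- structure(
    list(Tdist = methods::as(Tdist, "CsparseMatrix"),
         Tdist_inv = methods::as(Tinv, "CsparseMatrix"),
         gamma = gamma, M = M,
         subsets = subs, multiplicity = Q,
         distilled_model = distilled,
         distilled_labels = feature_labels(distilled),
         blocks = dec$blocks, model = model),
    class = "sfr_distillation")
  if (verify) {
    X <- design_matrix(model, cap)
    Z <- as.matrix(Matrix::tcrossprod(res$Tdist, X))  # (M x n) transformed
    if (gamma > 0 && max(abs(Z[M - gamma + seq_len(gamma), ])) != 0) {
      stop("internal error: distillation zero block is not exact")
    }
    D <- design_matrix(distilled, cap)
    if (M > gamma && max(abs(t(Z[seq_len(M - gamma), , drop = FALSE]) - D))
        != 0) {
      stop("internal error: distilled block does not match simplex embedding")
    }
  }
  res
}

#' @export
print.sfr_distillation <- function(x, ...) {
  cat(sprintf("Embedding distillation: M = %g, gamma = %g, K = %d distinct subsets\n",
              x$M, x$gamma, length(x$subsets)))
  cat(sprintf("  nonzeros in Tdist: %d (all +/-1)\n",
              Matrix::nnzero(x$Tdist)))
  mult <- x$multiplicity
  redun <- sum(mult > 1L)
  cat(sprintf("  redundant subsets (Q_k > 1): %d\n", redun))
  invisible(x)
}

# Distinct subsets B_k with multiplicities Q_k and both analytic gauge
# counts, without building any matrix.
gauge_count_detail <- function(model) {
  stopifnot(inherits(model, "sfr_model"))
  a <- model$alpha
  counts <- new.env(parent = emptyenv())
  reps <- new.env(parent = emptyenv())
  add <- function(B) {
    k <- paste0("k", subset_key(B))
    counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
    if (is.null(reps[[k]])) reps[[k]] <- B
  }
  for (A in model$sets) {
    if (model$flavor == "simplex") {
      add(A)
    } else {
      m <- length(A)
      if (m == 0L) add(integer(0))
      else for (mask in 0:(2^m - 1L)) {
        add(A[bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0L])
      }
    }
  }
  keys <- ls(counts)
  subs <- lapply(keys, function(k) reps[[k]])
  ord <- subset_order(subs)
  subs <- subs[ord]
  Q <- vapply(keys, function(k) counts[[k]], integer(1))[ord]
  sizes <- lengths(subs)
  M <- count_params(model)
  gamma_diff <- M - sum((a - 1)^sizes)             # M minus distilled dim
  gamma_mult <- sum((Q - 1) * (a - 1)^sizes)       # redundancy count
  stopifnot(isTRUE(all.equal(gamma_diff, gamma_mult)))
  list(subsets = subs, Q = Q, sizes = sizes, M = M,
       gamma = gamma_diff, gamma_by_difference = gamma_diff,
       gamma_by_multiplicity = gamma_mult)
}

#' Number of gauge freedoms, analytically
#'
#' Computes the distinct position subsets `B_k` occurring among (subsets
#' of) the model's position sets and their multiplicities `Q_k`, and
#' evaluates the gauge count both as `M - sum_k (alpha-1)^|B_k|` and as
#' `sum_k (Q_k - 1)(alpha-1)^|B_k|` (the two must agree; the function
#' errors otherwise). Purely combinatorial: no matrix is built, so this
#' scales to large `L` for fixed interaction order.
#'
#' @param model An `"sfr_model"`.
#' @return Numeric gauge count `gamma`.
#' @examples
#' count_gauge(sfr_preset("pairwise", "ACGT", 10))  # L + choose(L,2)(2a-1)
#' @export
count_gauge <- function(model) {
  gauge_count_detail(model)$gamma
}

#' Enumerate all equivariance classes of linear models
#'
#' Every PSCP-equivariant linear model is equivalent (same expressivity) to
#' exactly one distilled model: a simplex model over a *set* of distinct
#' position subsets. There are `2^L` irreducible embeddings (one per subset
#' of positions, trivial or simplex factors per position), hence
#' `2^(2^L)` inequivalent models.
#'
#' @param L Sequence length (at most 4; the count is doubly exponential).
#' @param alphabet Alphabet used to materialize each class as a concrete
#'   simplex-flavor `"sfr_model"`; the classes themselves do not depend on
#'   it.
#' @return List of `2^(2^L)` simplex `"sfr_model"` objects (the first is
#'   the degenerate empty model).
#' @export
enumerate_model_classes <- function(L, alphabet = c("A", "B")) {
  L <- as.integer(L)
  if (L > 4L) stop("L too large: class count is 2^(2^L)")
  nsub <- 2^L
  power <- lapply(0:(nsub - 1L), function(mask)
    which(bitwAnd(mask, 2^(seq_len(L) - 1L)) > 0L))
  power <- power[subset_order(power)]
  lapply(0:(2^nsub - 1L), function(fam) {
    members <- power[bitwAnd(fam, 2^(seq_len(nsub) - 1L)) > 0L]
    sfr_model(alphabet, L, "simplex", members)
  })
}
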