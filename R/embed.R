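#' Single-position one-hot embedding
#'
#' The indicator vector of dimension `alpha`: 1 at the index of `c` in the
#' alphabet, 0 elsewhere. The sum of the embeddings over all characters is
#' the all-ones vector, the linear dependency from which gauge freedoms of
#' one-hot models ultimately derive.
#'
#' @param c A single character in the alphabet.
#' @param alphabet Alphabet (see [as_alphabet()]).
#' @return Integer vector of length `alpha`.
#' @examples
#' onehot_single("A", c("A", "B", "C"))  # 1 0 0
#' @export
onehot_single <- function(c, alphabet) {
  alphabet <- as_alphabet(alphabet)
  i <- match(c, alphabet)
  if (is.na(i)) stop("unknown character: ", c)
  v <- integer(length(alphabet))
  v[i] <- 1L
  v
}

#' Single-position simplex embedding
#'
#' Zero-centered encoding of dimension `alpha - 1`: character `c_i` with
#' `i < alpha` maps to the i-th standard basis vector, and the reference
#' character `c_alpha` (the last alphabet character) maps to the
#' all-minus-one vector. The embeddings of all characters sum to zero, so
#' simplex features carry no linear dependency.
#'
#' @inheritParams onehot_single
#' @return Integer vector of length `alpha - 1`.
#' @examples
#' simplex_single("A", c("A", "B", "C"))  # 1 0
#' simplex_single("C", c("A", "B", "C"))  # -1 -1
#' @export
simplex_single <- function(c, alphabet) {
  alphabet <- as_alphabet(alphabet)
  a <- length(alphabet)
  i <- match(c, alphabet)
  if (is.na(i)) stop("unknown character: ", c)
  if (i == a) return(rep(-1L, a - 1L))
  v <- integer(a - 1L)
  v[i] <- 1L
  v
}

single_embedding <- function(c, model) {
  if (model$flavor == "one-hot") onehot_single(c, model$alphabet)
  else simplex_single(c, model$alphabet)
}

#' Embed a sequence into feature space
#'
#' Computes the model's feature vector `x(s)`: the direct sum over position
#' sets (in listed order) of the Kronecker product over the set's positions
#' (ascending, earlier positions varying slowest) of the single-position
#' embedding. An empty position set contributes the 1-dimensional constant
#' feature `(1)`.
#'
#' @param model An `"sfr_model"`.
#' @param s A single sequence (string of length `model$L`).
#' @return Numeric vector of length `M`, named by feature labels.
#' @export
embed_sequence <- function(model, s) {
  stopifnot(inherits(model, "sfr_model"))
  idx <- seq_to_idx(s, model$alphabet)
  if (length(idx) != model$L) {
    stop(sprintf("sequence length %d does not match model length %d",
                 length(idx), model$L))
  }
  singles <- lapply(strsplit(s, "")[[1L]], single_embedding, model = model)
  blocks <- lapply(model$sets, function(A) {
    v <- 1
    for (l in A) v <- kronecker(v, singles[[l]])
    as.numeric(v)
  })
  x <- unlist(blocks, use.names = FALSE)
  if (is.null(x)) x <- numeric(0)
  names(x) <- feature_labels(model)
  x
}

#' Embedding matrix for a set of sequences
#'
#' Row `i` is `embed_sequence(model, sequences[i])`, computed blockwise with
#' row-wise Kronecker products (no per-sequence loop over features).
#'
#' @param model An `"sfr_model"`.
#' @param sequences Character vector of sequences.
#' @return Numeric matrix, `length(sequences) x M`, with sequence rownames
#'   and feature-label colnames.
#' @export
embedding_matrix <- function(model, sequences) {
  stopifnot(inherits(model, "sfr_model"))
  n <- length(sequences)
  a <- model$alpha
  d <- if (model$flavor == "one-hot") a else a - 1L
  idx <- t(vapply(sequences, seq_to_idx, integer(model$L),
                  alphabet = model$alphabet))
  if (model$L == 1L) idx <- matrix(idx, ncol = 1L)
  # per-position single-embedding design blocks, n x d each
  base <- t(vapply(model$alphabet, single_embedding, numeric(d),
                   model = model))
  if (a == 2L && model$flavor == "simplex") base <- matrix(base, ncol = 1L)
  pos_block <- lapply(seq_len(model$L), function(l)
    base[idx[, l], , drop = FALSE])
  blocks <- lapply(model$sets, function(A) {
    D <- matrix(1, n, 1L)
    for (l in A) {
      B <- pos_block[[l]]
      D <- D[, rep(seq_len(ncol(D)), each = ncol(B)), drop = FALSE] *
        B[, rep(seq_len(ncol(B)), times = ncol(D)), drop = FALSE]
    }
    D
  })
  out <- if (length(blocks)) do.call(cbind, blocks)
         else matrix(0, n, 0L)
  dimnames(out) <- list(sequences, feature_labels(model))
  out
}

#' Full design matrix over the whole sequence space
#'
#' The `alpha^L x M` matrix whose rows are the embeddings of all sequences
#' in enumeration order. Its rank deficit `M - rank` equals the number of
#' gauge freedoms; the gauge space is its null space.
#'
#' @inheritParams embed_sequence
#' @param cap Enumeration cap passed to [enumerate_sequences()].
#' @export
design_matrix <- function(model, cap = 1e6) {
  stopifnot(inherits(model, "sfr_model"))
  embedding_matrix(model, enumerate_sequences(model$alphabet, model$L, cap))
}

#' Evaluate a linear model on sequences
#'
#' Computes `f(s; theta) = theta' x(s)` for each sequence.
#'
#' @param model An `"sfr_model"`.
#' @param theta Numeric parameter vector of length `M` (if named, names
#'   must match the model's feature labels; order is fixed by position).
#' @param s Character vector of sequences.
#' @return Numeric vector of predictions, named by sequence.
#' @export
evaluate_model <- function(model, theta, s) {
  stopifnot(inherits(model, "sfr_model"))
  theta <- check_theta(model, theta)
  X <- embedding_matrix(model, s)
  drop(X %*% theta)
}

check_theta <- function(model, theta) {
  if (length(theta) != model$M) {
    stop(sprintf("parameter vector has length %d, model has M = %g",
                 length(theta), model$M))
  }
  if (!all(is.finite(theta))) stop("parameters must be finite")
  if (!is.null(names(theta))) {
    labs <- feature_labels(model)
    if (!identical(names(theta), labs)) {
      if (setequal(names(theta), labs)) theta <- theta[labs]
      else stop("parameter names do not match model feature labels")
    }
  }
  as.numeric(theta)
}
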