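#' Permutation representation of a single-position character permutation
#'
#' The `alpha x alpha` permutation matrix `R` satisfying
#' `R %*% onehot_single(c) == onehot_single(h(c))` for every character:
#' column `j` is the one-hot embedding of the image of the j-th character.
#'
#' @param perm Named character vector mapping each alphabet character to its
#'   image (a bijection), or one entry of `pscp()$perms`.
#' @param alphabet Alphabet (see [as_alphabet()]).
#' @return Integer permutation matrix.
#' @examples
#' perm_rep_single(c(A = "C", B = "B", C = "A"), c("A", "B", "C"))
#' @export
perm_rep_single <- function(perm, alphabet) {
  alphabet <- as_alphabet(alphabet)
  perm <- check_perm(perm, alphabet)
  a <- length(alphabet)
  R <- matrix(0L, a, a)
  for (j in seq_len(a)) R[match(perm[[alphabet[j]]], alphabet), j] <- 1L
  R
}

#' Standard (simplex) representation of a character permutation
#'
#' The unique `(alpha-1) x (alpha-1)` integer matrix `R` with
#' `R %*% simplex_single(c) == simplex_single(h(c))` for all characters.
#' Because the first `alpha - 1` simplex vectors form the standard basis,
#' the matrix is assembled by solving against them directly: column `i` is
#' the simplex embedding of the image of character `c_i`. This construction
#' is independent of the similarity transformation used in distillation, so
#' the Maschke identity remains a genuine cross-check.
#'
#' @inheritParams perm_rep_single
#' @return Integer matrix, generally not a permutation matrix.
#' @examples
#' simplex_rep_single(c(A = "C", B = "B", C = "A"), c("A", "B", "C"))
#' # matrix(c(-1, -1, 0, 1), 2)
#' @export
simplex_rep_single <- function(perm, alphabet) {
  alphabet <- as_alphabet(alphabet)
  perm <- check_perm(perm, alphabet)
  a <- length(alphabet)
  cols <- vapply(seq_len(a - 1L), function(i)
    simplex_single(perm[[alphabet[i]]], alphabet), integer(a - 1L))
  matrix(cols, nrow = a - 1L)
}

check_perm <- function(perm, alphabet) {
  if (is.null(names(perm))) names(perm) <- alphabet
  perm <- perm[alphabet]
  if (anyNA(perm) || !setequal(perm, alphabet)) {
    stop("perm must be a bijection of the alphabet")
  }
  perm
}

#' Representation of a PSCP element on a model's feature space
#'
#' The `M x M` matrix `R(h)` with `embed_sequence(model, hs) ==
#' R(h) %*% embed_sequence(model, s)` for all sequences: the direct sum
#' over position sets of Kronecker products of single-position
#' representation matrices (flavor-matched). For one-hot models every
#' `R(h)` is a permutation matrix; for simplex models with `alpha >= 3`
#' it generally is not.
#'
#' @param model An `"sfr_model"`.
#' @param h A `"pscp"` element with matching alphabet and length.
#' @return Sparse integer matrix (`Matrix::dgCMatrix`).
#' @export
model_rep <- function(model, h) {
  stopifnot(inherits(model, "sfr_model"), inherits(h, "pscp"),
            h$L == model$L, identical(h$alphabet, model$alphabet))
  single <- lapply(h$perms, function(p) {
    if (model$flavor == "one-hot") perm_rep_single(p, model$alphabet)
    else simplex_rep_single(p, model$alphabet)
  })
  blocks <- lapply(model$sets, function(A) {
    R <- matrix(1, 1L, 1L)
    for (l in A) R <- R %x% single[[l]]
    methods::as(R, "CsparseMatrix")
  })
  if (length(blocks) == 0L) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                x = numeric(0), dims = c(0L, 0L)))
  }
  Matrix::bdiag(blocks)
}

#' Compensating parameter transformation
#'
#' Returns `(R(h)^-1)' theta`, the parameter vector that reproduces the
#' original model after the sequence transformation `h`:
#' `f(s; theta) == f(hs; transform_parameters(model, h, theta))`.
#' The inverse is taken exactly as the representation of `h^-1`.
#'
#' @inheritParams model_rep
#' @param theta Numeric parameter vector of length `M`.
#' @return Numeric vector of length `M`, named by feature labels.
#' @export
transform_parameters <- function(model, h, theta) {
  theta <- check_theta(model, theta)
  Rinv <- model_rep(model, pscp_inverse(h))
  out <- as.numeric(Matrix::crossprod(Rinv, theta))
  names(out) <- feature_labels(model)
  out
}

#' Check the single-position Maschke identity
#'
#' Verifies that conjugating the one-hot permutation representation by the
#' similarity matrix `T` block-diagonalizes it into the trivial
#' representation `(1)` and the simplex representation:
#' `T R_ohe(h) T^-1 == (1) + R_sim(h)` (direct sum).
#'
#' @inheritParams perm_rep_single
#' @param tol Absolute tolerance (the conjugation involves the rational
#'   inverse of `T`).
#' @return `TRUE` or `FALSE`.
#' @export
check_maschke_single <- function(alphabet, perm, tol = 1e-9) {
  alphabet <- as_alphabet(alphabet)
  a <- length(alphabet)
  Tm <- similarity_T(a)
  lhs <- Tm$T %*% perm_rep_single(perm, alphabet) %*% Tm$Tinv
  rhs <- matrix(0, a, a)
  rhs[1L, 1L] <- 1
  rhs[2:a, 2:a] <- simplex_rep_single(perm, alphabet)
  max(abs(lhs - rhs)) < tol
}
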