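# Brute-force certification, deliberately independent of the distillation
# code path: everything here works from the dense design matrix via SVD.

design_rank <- function(X, tol = 1e-9) {
  if (ncol(X) == 0L) return(0L)
  d <- svd(X, nu = 0, nv = 0)$d
  sum(d > tol * max(d, 1))
}

#' Null-space dimension of the design matrix
#'
#' `M - rank(X)` computed by singular value decomposition over the full
#' enumerated sequence space. This equals the number of gauge freedoms and
#' serves as the independent oracle for [count_gauge()] and [distill()].
#'
#' @param model An `"sfr_model"`.
#' @param cap Enumeration cap.
#' @param tol Relative singular-value tolerance; entries of the design
#'   matrix are in `{-1, 0, 1}` so rank is robust at these sizes.
#' @return Integer null-space dimension.
#' @export
nullspace_dim <- function(model, cap = 1e6, tol = 1e-9) {
  stopifnot(inherits(model, "sfr_model"))
  X <- design_matrix(model, cap)
  ncol(X) - design_rank(X, tol)
}

#' Orthonormal basis of the design-matrix null space
#'
#' Right singular vectors belonging to (numerically) zero singular values.
#' Used only for span comparisons against the sparse gauge basis.
#'
#' @inheritParams nullspace_dim
#' @return `M x gamma` matrix with orthonormal columns (0 columns when the
#'   model has no gauge freedoms).
#' @export
nullspace_basis <- function(model, cap = 1e6, tol = 1e-9) {
  stopifnot(inherits(model, "sfr_model"))
  X <- design_matrix(model, cap)
  M <- ncol(X)
  if (M == 0L) return(matrix(0, 0L, 0L))
  s <- svd(X, nu = 0, nv = M)
  d <- c(s$d, rep(0, M - length(s$d)))
  null_cols <- d <= tol * max(d, 1)
  s$v[, null_cols, drop = FALSE]
}

#' Test equality of two models' expressivity
#'
#' Two models describe the same set of sequence-function relationships iff
#' their design matrices have equal column spans. Checked via ranks of the
#' individual and concatenated matrices.
#'
#' @param modelA,modelB Models over the same alphabet and length.
#' @param cap Enumeration cap.
#' @param tol Rank tolerance.
#' @return `TRUE` or `FALSE`.
#' @export
span_equal <- function(modelA, modelB, cap = 1e6, tol = 1e-9) {
  stopifnot(inherits(modelA, "sfr_model"), inherits(modelB, "sfr_model"),
            identical(modelA$alphabet, modelB$alphabet),
            modelA$L == modelB$L)
  XA <- design_matrix(modelA, cap)
  XB <- design_matrix(modelB, cap)
  rA <- design_rank(XA, tol)
  rB <- design_rank(XB, tol)
  rA == rB && design_rank(cbind(XA, XB), tol) == rA
}

#' Certify a model's distillation against the brute-force oracle
#'
#' Runs the full consistency suite for one model: parameter count versus
#' embedding dimension, analytic gauge count (both formulas) versus the
#' oracle's null-space dimension, the exact distillation certificate (zero
#' block and distilled simplex block over all sequences), the `{-1,0,+1}`
#' entry claim, invertibility of `Tdist`, and span agreement between the
#' sparse gauge basis and the oracle null space.
#'
#' @param model An `"sfr_model"`.
#' @param cap Enumeration cap.
#' @param tol Numerical tolerance.
#' @return A data frame with columns `check` and `pass`; attribute
#'   `"distillation"` carries the distillation object.
#' @export
verify_model <- function(model, cap = 1e6, tol = 1e-9) {
  stopifnot(inherits(model, "sfr_model"))
  d <- distill(model)
  X <- design_matrix(model, cap)
  M <- model$M
  g <- d$gamma
  checks <- list()
  add <- function(name, pass) checks[[length(checks) + 1L]] <<-
    data.frame(check = name, pass = pass, stringsAsFactors = FALSE)

  add("M equals embedding dimension",
      count_params(model) == M && ncol(X) == M)
  detail <- gauge_count_detail(model)
  add("gauge count: difference formula agrees with multiplicity formula",
      detail$gamma_by_difference == detail$gamma_by_multiplicity)
  add("gauge count equals oracle null-space dimension",
      detail$gamma == nullspace_dim(model, cap, tol))
  Z <- as.matrix(Matrix::tcrossprod(d$Tdist, X))
  zero_ok <- g == 0 || max(abs(Z[M - g + seq_len(g), , drop = FALSE])) == 0
  add("last gamma coordinates of Tdist x(s) vanish for all s", zero_ok)
  D <- design_matrix(d$distilled_model, cap)
  top_ok <- M == g ||
    max(abs(t(Z[seq_len(M - g), , drop = FALSE]) - D)) == 0
  add("top block equals distilled simplex embedding", top_ok)
  nz <- abs(d$Tdist@x)
  add("all nonzero entries of Tdist are +/-1",
      length(nz) == 0 || all(nz == 1))
  add("Tdist %*% Tdist_inv is the identity",
      M == 0 ||
        max(abs(d$Tdist %*% d$Tdist_inv - Matrix::Diagonal(M))) < tol)
  gb <- gauge_basis(d)
  add("gauge basis annihilates the design matrix",
      g == 0 || max(abs(X %*% Matrix::t(gb))) == 0)
  nb <- nullspace_basis(model, cap, tol)
  span_ok <- ncol(nb) == g &&
    (g == 0 ||
       max(abs(nb - Matrix::t(gb) %*%
                 solve(as.matrix(gb %*% Matrix::t(gb)),
                       as.matrix(gb %*% nb)))) < 1e-6)
  add("gauge basis spans the oracle null space", span_ok)
  out <- do.call(rbind, checks)
  attr(out, "distillation") <- d
  out
}
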