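#' Sparse basis of the gauge space
#'
#' The gauge space G — directions `g` in parameter space with
#' `g' x(s) = 0` for every sequence, i.e. parameter changes invisible to
#' the model — is spanned by the last `gamma` rows of the distillation
#' matrix. All entries are in `{-1, 0, +1}`.
#'
#' @param distres An `"sfr_distillation"` from [distill()].
#' @return Sparse `gamma x M` matrix; columns named by feature labels.
#' @export
gauge_basis <- function(distres) {
  stopifnot(inherits(distres, "sfr_distillation"))
  M <- distres$M
  g <- distres$gamma
  B <- distres$Tdist[M - g + seq_len(g), , drop = FALSE]
  colnames(B) <- feature_labels(distres$model)
  if (g > 0) rownames(B) <- paste0("g", seq_len(g))
  B
}

#' Test whether a vector is a gauge freedom
#'
#' Exhaustive check of `g' x(s) = 0` over all `alpha^L` sequences. Exact
#' for integer-valued `g` (all arithmetic stays integral); otherwise an
#' absolute tolerance applies.
#'
#' @param model An `"sfr_model"`.
#' @param g Numeric vector of length `M`.
#' @param cap Enumeration cap.
#' @param tol Absolute tolerance for non-integer `g`.
#' @return `TRUE` or `FALSE`.
#' @export
is_gauge_vector <- function(model, g, cap = 1e6, tol = 1e-9) {
  stopifnot(inherits(model, "sfr_model"), length(g) == model$M)
  X <- design_matrix(model, cap)
  r <- as.numeric(X %*% as.numeric(g))
  if (all(g == round(g))) max(abs(r)) == 0 else max(abs(r)) < tol
}

#' Gauge-fixing projection matrix
#'
#' The idempotent matrix `P = t(Tdist) D t(Tdist^-1)`, where `D` keeps the
#' first `M - gamma` (distilled) coordinates. `P` leaves every prediction
#' unchanged (`f(s; P theta) = f(s; theta)`), annihilates the gauge basis,
#' and its image is a linear gauge of dimension `M - gamma` (the "distilled
#' gauge": the redundant coordinates of `t(Tdist^-1) theta` are zeroed).
#' This is one valid linear gauge; it is not claimed to coincide with the
#' zero-sum gauge (see [zero_sum_check()]).
#'
#' @inheritParams gauge_basis
#' @return Sparse `M x M` projection matrix.
#' @export
projection_matrix <- function(distres) {
  stopifnot(inherits(distres, "sfr_distillation"))
  M <- distres$M
  keep <- rep(c(1, 0), c(M - distres$gamma, distres$gamma))
  D <- Matrix::Diagonal(M, keep)
  methods::as(
    Matrix::t(distres$Tdist) %*% D %*% Matrix::t(distres$Tdist_inv),
    "CsparseMatrix")
}

#' Project parameters onto the distilled gauge
#'
#' Returns `P theta`: equivalent parameters (identical predictions on every
#' sequence) with all redundant distilled coordinates set to zero. The map
#' is idempotent and annihilates gauge directions.
#'
#' @inheritParams gauge_basis
#' @param theta Numeric parameter vector of length `M`.
#' @return Numeric vector of length `M`, named by feature labels.
#' @export
project_parameters <- function(distres, theta) {
  stopifnot(inherits(distres, "sfr_distillation"))
  theta <- check_theta(distres$model, theta)
  M <- distres$M
  v <- as.numeric(Matrix::crossprod(distres$Tdist_inv, theta))
  if (distres$gamma > 0) v[M - distres$gamma + seq_len(distres$gamma)] <- 0
  out <- as.numeric(Matrix::crossprod(distres$Tdist, v))
  names(out) <- feature_labels(distres$model)
  out
}

#' Zero-sum gauge check for the pairwise one-hot model
#'
#' Tests whether a parameter vector lies in the classical zero-sum gauge:
#' additive parameters at each position sum to zero over characters, and
#' pairwise parameters sum to zero when marginalized over the characters at
#' either position (for every fixed partner character).
#'
#' @param model The pairwise one-hot preset (`sfr_preset("pairwise", ...)`);
#'   other models are an error.
#' @param theta Numeric parameter vector of length `M`.
#' @param tol Absolute tolerance on each marginal sum.
#' @return `TRUE` or `FALSE`.
#' @export
zero_sum_check <- function(model, theta, tol = 1e-9) {
  stopifnot(inherits(model, "sfr_model"))
  if (model$flavor != "one-hot" || !is_pairwise_structure(model)) {
    stop("zero_sum_check applies to the pairwise one-hot model only")
  }
  theta <- check_theta(model, theta)
  a <- model$alpha
  L <- model$L
  for (j in seq_along(model$sets)) {
    A <- model$sets[[j]]
    off <- model$block_offset[j]
    if (length(A) == 1L) {
      if (abs(sum(theta[off + seq_len(a)])) > tol) return(FALSE)
    } else if (length(A) == 2L) {
      Th <- matrix(theta[off + seq_len(a^2)], nrow = a, byrow = TRUE)
      # rows index the first position's character (kron-major order)
      if (max(abs(rowSums(Th))) > tol) return(FALSE)
      if (max(abs(colSums(Th))) > tol) return(FALSE)
    }
  }
  TRUE
}

is_pairwise_structure <- function(model) {
  L <- model$L
  want <- c(list(integer(0)), lapply(seq_len(L), identity),
            if (L >= 2L) {
              cm <- utils::combn(L, 2L)
              lapply(seq_len(ncol(cm)), function(i) cm[, i])
            } else list())
  identical(lapply(model$sets, as.integer), lapply(want, as.integer))
}
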