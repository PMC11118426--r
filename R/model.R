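#' Specify a generalized one-hot or simplex model
#'
#' A linear sequence-function model is specified by an alphabet, a sequence
#' length `L`, an embedding flavor, and an ordered list of position sets
#' `A_1, ..., A_J` (subsets of `1:L`; the empty set is allowed and denotes
#' the constant feature; duplicate sets are allowed). The model's embedding
#' is the direct sum over `j` of the Kronecker product over `l` in `A_j`
#' (ascending) of the single-position embedding, one-hot (dimension `alpha`
#' per position) or simplex (dimension `alpha - 1` per position).
#'
#' The number of parameters is `M = sum_j alpha^|A_j|` for one-hot flavor
#' and `sum_j (alpha-1)^|A_j|` for simplex flavor.
#'
#' @param alphabet Alphabet (see [as_alphabet()]).
#' @param L Sequence length.
#' @param flavor `"one-hot"` or `"simplex"`.
#' @param sets List of integer vectors, each a subset of `1:L`. An empty
#'   list is permitted and yields the degenerate model with `M = 0`.
#' @return An object of class `"sfr_model"` with fields `alphabet`, `alpha`,
#'   `L`, `flavor`, `sets`, `M`, `labels` (feature labels, contractual for
#'   TSV I/O), `block_dim` and `block_offset`.
#' @examples
#' m <- sfr_model("AB", 2, "one-hot", list(integer(0), 1, 2, c(1, 2)))
#' m$M       # 9
#' m$labels  # "theta_0" "theta_1:A" ... "theta_1,2:BB"
#' @seealso [sfr_preset()] for the standard model families.
#' @export
sfr_model <- function(alphabet, L, flavor = c("one-hot", "simplex"),
                      sets = list(integer(0))) {
  alphabet <- as_alphabet(alphabet)
  flavor <- match.arg(flavor)
  L <- as.integer(L)
  stopifnot(L >= 1L)
  if (!is.list(sets)) sets <- list(sets)
  sets <- lapply(sets, function(A) {
    A <- as.integer(A)
    if (anyDuplicated(A)) stop("position set has repeated positions: ",
                               paste(A, collapse = ","))
    if (length(A) && (min(A) < 1L || max(A) > L)) {
      stop("position out of range 1..", L, ": ", paste(A, collapse = ","))
    }
    sort(A)
  })
  a <- length(alphabet)
  d <- if (flavor == "one-hot") a else a - 1L
  block_dim <- vapply(sets, function(A) d^length(A), numeric(1))
  M <- sum(block_dim)
  block_offset <- cumsum(c(0, block_dim))[seq_along(sets)]
  obj <- structure(
    list(alphabet = alphabet, alpha = a, L = L, flavor = flavor,
         sets = sets, M = M, block_dim = block_dim,
         block_offset = block_offset),
    class = "sfr_model")
  # labels are materialized only at workable sizes; counting-only use of
  # huge specs (e.g. pairwise at L in the thousands) stays cheap
  if (M <= 1e5) obj$labels <- feature_labels(obj)
  obj
}

#' Feature labels of a model
#'
#' Label syntax (contractual for parameter TSVs): the constant block is
#' `"theta_0"`; a one-hot block on positions 1,3 yields
#' `"theta_1,3:AC"`-style labels (character tuple, position-major); a
#' simplex block yields `"theta_1,3:1,2"` with indices in `1..alpha-1`.
#' Duplicate position sets get a `"#<ordinal>"` suffix from the second copy
#' on, keeping labels unique.
#'
#' @param model An `"sfr_model"`.
#' @return Character vector of length `M`, in embedding order.
#' @export
feature_labels <- function(model) {
  a <- model$alpha
  keys <- vapply(model$sets, function(A) paste(A, collapse = ","),
                 character(1))
  seen <- new.env(parent = emptyenv())
  labs <- vector("list", length(model$sets))
  for (j in seq_along(model$sets)) {
    A <- model$sets[[j]]
    key <- keys[j]
    n_prev <- if (is.null(seen[[paste0("k", key)]])) 0L
              else seen[[paste0("k", key)]]
    seen[[paste0("k", key)]] <- n_prev + 1L
    suffix <- if (n_prev > 0L) paste0("#", n_prev + 1L) else ""
    if (length(A) == 0L) {
      labs[[j]] <- paste0("theta_0", suffix)
      next
    }
    if (model$flavor == "one-hot") {
      tuples <- char_tuples(model$alphabet, length(A))
      body <- apply(tuples, 1L, paste, collapse = "")
    } else {
      tuples <- char_tuples(as.character(seq_len(a - 1L)), length(A))
      body <- apply(tuples, 1L, paste, collapse = ",")
    }
    labs[[j]] <- paste0("theta_", key, ":", body, suffix)
  }
  unlist(labs, use.names = FALSE)
}

# All m-tuples over `syms` in Kronecker order: first slot varies slowest.
char_tuples <- function(syms, m) {
  grid <- do.call(expand.grid,
                  c(rep(list(syms), m),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
  as.matrix(grid)[, m:1, drop = FALSE]
}

#' @export
print.sfr_model <- function(x, ...) {
  cat(sprintf("Linear %s model on {%s}^%d\n", x$flavor,
              paste(x$alphabet, collapse = ","), x$L))
  cat(sprintf("  J = %d position sets, M = %g parameters\n",
              length(x$sets), x$M))
  shown <- utils::head(x$sets, 8L)
  desc <- vapply(shown, function(A)
    if (length(A) == 0L) "{}" else paste0("{", paste(A, collapse = ","), "}"),
    character(1))
  cat("  sets:", paste(desc, collapse = " "),
      if (length(x$sets) > 8L) "..." else "", "\n")
  invisible(x)
}

#' @export
summary.sfr_model <- function(object, ...) {
  g <- gauge_count_detail(object)
  cat(sprintf("Linear %s model, alphabet size %d, L = %d\n",
              object$flavor, object$alpha, object$L))
  cat(sprintf("  parameters M       : %g\n", object$M))
  cat(sprintf("  distinct subsets K : %d\n", length(g$subsets)))
  cat(sprintf("  gauge freedoms     : %g\n", g$gamma))
  invisible(object)
}

#' Standard model families
#'
#' Builds the position-set list for the classical interaction structures:
#' `constant`, `additive`, `pairwise`, `nearest-neighbor`, `all-order`,
#' `all-adjacent`, and the parameterized families `K-order`,
#' `hierarchical-K-order`, `K-adjacent`, `hierarchical-K-adjacent`.
#' Blocks are listed constant first, then ascending interaction order,
#' then lexicographically by positions.
#'
#' @inheritParams sfr_model
#' @param name Preset name (see above).
#' @param K Interaction order for the `K-*` families.
#' @return An `"sfr_model"` with attribute `"preset"` set to `name`.
#' @examples
#' sfr_preset("pairwise", "ACGT", 5)
#' sfr_preset("K-order", "AB", 4, K = 2)
#' @export
sfr_preset <- function(name, alphabet, L,
                       flavor = c("one-hot", "simplex"), K = NULL) {
  flavor <- match.arg(flavor)
  L <- as.integer(L)
  singles <- lapply(seq_len(L), identity)
  pairs <- if (L >= 2L) {
    cm <- utils::combn(L, 2L)
    lapply(seq_len(ncol(cm)), function(i) cm[, i])
  } else list()
  windows <- function(k) lapply(seq_len(L - k + 1L), function(l)
    l:(l + k - 1L))
  ksubsets <- function(k) {
    if (k == 0L) return(list(integer(0)))
    cm <- utils::combn(L, k)
    lapply(seq_len(ncol(cm)), function(i) cm[, i])
  }
  need_K <- function() {
    if (is.null(K)) stop("preset '", name, "' requires K")
    K <- as.integer(K)
    if (K < 1L || K > L) stop("K must be in 1..L, got ", K)
    K
  }
  sets <- switch(
    name,
    "constant" = list(integer(0)),
    "additive" = c(list(integer(0)), singles),
    "pairwise" = c(list(integer(0)), singles, pairs),
    "nearest-neighbor" = c(list(integer(0)), singles,
                           if (L >= 2L) windows(2L) else list()),
    "all-order" = do.call(c, lapply(0:L, ksubsets)),
    "all-adjacent" = c(list(integer(0)),
                       do.call(c, lapply(seq_len(L), windows))),
    "K-order" = ksubsets(need_K()),
    "hierarchical-K-order" = do.call(c, lapply(0:need_K(), ksubsets)),
    "K-adjacent" = windows(need_K()),
    "hierarchical-K-adjacent" = c(list(integer(0)),
                                  do.call(c, lapply(seq_len(need_K()),
                                                    windows))),
    stop("unknown preset: ", name)
  )
  m <- sfr_model(alphabet, L, flavor, sets)
  attr(m, "preset") <- name
  m
}

#' Number of model parameters, combinatorially
#'
#' Computes `M = sum_j alpha^|A_j|` (one-hot) or `sum_j (alpha-1)^|A_j|`
#' (simplex) without constructing any matrix, so it works for large `L`.
#'
#' @param model An `"sfr_model"`.
#' @return Numeric count (exact for values below 2^53).
#' @export
count_params <- function(model) {
  stopifnot(inherits(model, "sfr_model"))
  d <- if (model$flavor == "one-hot") model$alpha else model$alpha - 1
  sum(d^lengths(model$sets))
}
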