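#' Validate an alphabet
#'
#' An alphabet is an ordered set of at least two distinct single characters.
#' The order is contractual: it fixes feature indexing throughout the
#' package, and the *last* character plays the role of the simplex reference
#' character (the one embedded as the all-minus-one vector).
#'
#' @param alphabet A character vector of single characters, or a single
#'   string which is split into characters (e.g. `"ACGT"`).
#' @return A character vector of distinct single characters.
#' @examples
#' as_alphabet("ACGT")
#' as_alphabet(c("A", "B", "C"))
#' @export
as_alphabet <- function(alphabet) {
  if (length(alphabet) == 1L && nchar(alphabet) > 1L) {
    alphabet <- strsplit(alphabet, "")[[1L]]
  }
  alphabet <- as.character(alphabet)
  if (length(alphabet) < 2L) {
    stop("alphabet must contain at least 2 characters (alpha >= 2)")
  }
  if (anyDuplicated(alphabet)) {
    stop("alphabet characters must be distinct: ",
         paste(unique(alphabet[duplicated(alphabet)]), collapse = ", "))
  }
  if (any(nchar(alphabet) != 1L)) {
    stop("alphabet entries must be single characters")
  }
  alphabet
}

#' Enumerate all sequences of a given length
#'
#' Returns all `alpha^L` sequences over `alphabet` in lexicographic order of
#' character indices (first position most significant). This order is the
#' row order of every design matrix produced by the package.
#'
#' @param alphabet Alphabet (see [as_alphabet()]).
#' @param L Sequence length (positive integer).
#' @param cap Maximum number of sequences to enumerate; exceeded sizes are
#'   an error rather than an attempt to allocate.
#' @return Character vector of length `alpha^L`.
#' @examples
#' enumerate_sequences(c("A", "B"), 2)  # "AA" "AB" "BA" "BB"
#' @export
enumerate_sequences <- function(alphabet, L, cap = 1e6) {
  alphabet <- as_alphabet(alphabet)
  L <- as.integer(L)
  stopifnot(L >= 1L)
  a <- length(alphabet)
  n <- a^L
  if (n > cap) {
    stop(sprintf("sequence space too large: alpha^L = %g exceeds cap %g",
                 n, cap))
  }
  # expand.grid varies its first factor fastest; feed positions in reverse
  # so that the last sequence position varies fastest (lexicographic order).
  grid <- do.call(expand.grid,
                  c(rep(list(seq_len(a)), L),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
  idx <- as.matrix(grid)[, L:1, drop = FALSE]
  apply(idx, 1L, function(i) paste(alphabet[i], collapse = ""))
}

seq_to_idx <- function(s, alphabet) {
  ch <- strsplit(s, "")[[1L]]
  i <- match(ch, alphabet)
  if (anyNA(i)) {
    stop("sequence contains characters outside the alphabet: ",
         paste(unique(ch[is.na(i)]), collapse = ", "))
  }
  i
}

#' Position-specific character permutations (PSCP)
#'
#' A PSCP group element is a tuple of `L` permutations of the alphabet, one
#' per sequence position, acting on sequences position by position. Each
#' permutation is stored as a named character mapping (name = from, value =
#' to), so elements do not depend on alphabet ordering.
#'
#' @param perms List of `L` named character vectors, each a bijection of the
#'   alphabet onto itself.
#' @param alphabet Alphabet the permutations act on.
#' @return An object of class `"pscp"`.
#' @seealso [pscp_identity()], [random_pscp()], [apply_pscp()]
#' @export
pscp <- function(perms, alphabet) {
  alphabet <- as_alphabet(alphabet)
  stopifnot(is.list(perms), length(perms) >= 1L)
  perms <- lapply(perms, function(p) {
    if (is.null(names(p))) names(p) <- alphabet
    p <- p[alphabet]
    if (anyNA(p) || !setequal(p, alphabet)) {
      stop("each position permutation must be a bijection of the alphabet")
    }
    p
  })
  structure(list(perms = perms, alphabet = alphabet, L = length(perms)),
            class = "pscp")
}

#' @export
print.pscp <- function(x, ...) {
  cat(sprintf("PSCP element on alphabet {%s}, L = %d\n",
              paste(x$alphabet, collapse = ","), x$L))
  for (l in seq_len(x$L)) {
    p <- x$perms[[l]]
    moved <- p[names(p) != p]
    cat(sprintf("  position %d: %s\n", l,
                if (length(moved) == 0) "identity"
                else paste(names(moved), "->", moved, collapse = ", ")))
  }
  invisible(x)
}

#' Identity element of the PSCP group
#' @inheritParams pscp
#' @param L Sequence length.
#' @export
pscp_identity <- function(alphabet, L) {
  alphabet <- as_alphabet(alphabet)
  p <- stats::setNames(alphabet, alphabet)
  pscp(rep(list(p), L), alphabet)
}

#' Compose two PSCP elements
#'
#' Returns the product `h1 h2`, acting on sequences as `h1(h2 s)`.
#' @param h1,h2 Objects of class `"pscp"` over the same alphabet and length.
#' @export
pscp_compose <- function(h1, h2) {
  stopifnot(inherits(h1, "pscp"), inherits(h2, "pscp"),
            h1$L == h2$L, identical(h1$alphabet, h2$alphabet))
  perms <- lapply(seq_len(h1$L), function(l) {
    p <- h1$perms[[l]][h2$perms[[l]]]
    names(p) <- names(h2$perms[[l]])
    p
  })
  pscp(perms, h1$alphabet)
}

#' Invert a PSCP element
#' @param h Object of class `"pscp"`.
#' @export
pscp_inverse <- function(h) {
  stopifnot(inherits(h, "pscp"))
  perms <- lapply(h$perms, function(p) stats::setNames(names(p), p))
  pscp(perms, h$alphabet)
}

#' Apply a PSCP transformation to sequences
#'
#' @param h Object of class `"pscp"`.
#' @param s Character vector of sequences, each of length `h$L`.
#' @return Character vector of transformed sequences (`h s`).
#' @examples
#' h <- pscp(rep(list(c(A = "C", B = "B", C = "A")), 3), c("A", "B", "C"))
#' apply_pscp(h, "ABC")  # "CBA"
#' @export
apply_pscp <- function(h, s) {
  stopifnot(inherits(h, "pscp"))
  vapply(s, function(si) {
    ch <- strsplit(si, "")[[1L]]
    if (length(ch) != h$L) {
      stop(sprintf("sequence length %d does not match PSCP length %d",
                   length(ch), h$L))
    }
    out <- vapply(seq_len(h$L), function(l) {
      v <- h$perms[[l]][[ch[l]]]
      if (is.null(v)) stop("character outside alphabet: ", ch[l])
      v
    }, character(1))
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Draw a uniformly random PSCP element
#'
#' Each position receives an independent uniformly random permutation of the
#' alphabet, so the draw is uniform over the whole group of order
#' `(alpha!)^L`.
#'
#' @inheritParams pscp_identity
#' @param seed Optional integer; if supplied the draw is deterministic and
#'   the caller's RNG state is left untouched.
#' @export
random_pscp <- function(alphabet, L, seed = NULL) {
  alphabet <- as_alphabet(alphabet)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  perms <- replicate(L, stats::setNames(sample(alphabet), alphabet),
                     simplify = FALSE)
  pscp(perms, alphabet)
}

#' Hamming distance between two sequences of equal length
#' @param s,t Sequences (single strings).
#' @export
hamming <- function(s, t) {
  a <- strsplit(s, "")[[1L]]
  b <- strsplit(t, "")[[1L]]
  stopifnot(length(a) == length(b))
  sum(a != b)
}

#' All permutations of an alphabet
#'
#' Enumerates the full character-permutation group at one position as a
#' list of named mappings (name = from, value = to). Intended for
#' exhaustive checks at small alphabet sizes (`alpha! <= 24` at
#' `alpha <= 4`).
#'
#' @inheritParams as_alphabet
#' @return List of `alpha!` named character vectors.
#' @export
all_permutations <- function(alphabet) {
  alphabet <- as_alphabet(alphabet)
  permute_idx <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in permute_idx(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  lapply(permute_idx(alphabet), function(p) stats::setNames(p, alphabet))
}
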