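#' Read a model specification from a JSON config
#'
#' The config carries `alphabet` (string), `L`, optional `flavor`
#' (default `"one-hot"`), and either `preset` (with optional `K`) or
#' explicit `position_sets` (list of position arrays; `[]` entries denote
#' the constant feature). Presets are expanded to explicit position sets on
#' read. Validation errors name the offending field.
#'
#' @param path Path to a JSON file.
#' @return An `"sfr_model"`.
#' @examples
#' cfg <- tempfile(fileext = ".json")
#' writeLines('{"alphabet":"ABC","L":3,"flavor":"one-hot","preset":"all-order"}', cfg)
#' read_model_config(cfg)$M  # 64
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  need <- function(field) {
    if (is.null(cfg[[field]])) stop("config field missing: ", field)
    cfg[[field]]
  }
  alphabet <- tryCatch(as_alphabet(need("alphabet")),
                       error = function(e)
                         stop("config field 'alphabet': ",
                              conditionMessage(e), call. = FALSE))
  L <- as.integer(need("L"))
  if (is.na(L) || L < 1L) stop("config field 'L' must be a positive integer")
  flavor <- if (is.null(cfg$flavor)) "one-hot" else cfg$flavor
  if (!flavor %in% c("one-hot", "simplex")) {
    stop("config field 'flavor' must be 'one-hot' or 'simplex'")
  }
  if (!is.null(cfg$preset)) {
    K <- if (is.null(cfg$K)) NULL else as.integer(cfg$K)
    m <- tryCatch(sfr_preset(cfg$preset, alphabet, L, flavor, K = K),
                  error = function(e)
                    stop("config field 'preset': ", conditionMessage(e),
                         call. = FALSE))
    return(m)
  }
  if (is.null(cfg$position_sets)) {
    stop("config needs either 'preset' or 'position_sets'")
  }
  sets <- lapply(cfg$position_sets, function(A) as.integer(unlist(A)))
  tryCatch(sfr_model(alphabet, L, flavor, sets),
           error = function(e)
             stop("config field 'position_sets': ", conditionMessage(e),
                  call. = FALSE))
}

#' Write a model specification as a JSON config
#'
#' Explicit position sets are written (presets are not re-inferred), so a
#' read/write round-trip reproduces the model exactly.
#'
#' @param model An `"sfr_model"`.
#' @param path Output path.
#' @export
write_model_config <- function(model, path) {
  stopifnot(inherits(model, "sfr_model"))
  cfg <- list(alphabet = paste(model$alphabet, collapse = ""),
              L = model$L, flavor = model$flavor,
              position_sets = lapply(model$sets, as.integer))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE)
  invisible(path)
}

#' Sparse-matrix I/O in MatrixMarket coordinate format
#'
#' Thin wrappers over [Matrix::writeMM()]/[Matrix::readMM()]; integer
#' values are written in the integer field and round-trips are exact. A
#' matrix with zero rows (an empty gauge basis) round-trips through the
#' pattern field.
#'
#' @param m A matrix or `Matrix` sparse matrix.
#' @param path File path (`.mtx`).
#' @return `read_sparse_matrix` returns a `dgCMatrix`.
#' @export
write_sparse_matrix <- function(m, path) {
  m <- methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(m, path)
  invisible(path)
}

#' @rdname write_sparse_matrix
#' @export
read_sparse_matrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  m <- Matrix::readMM(path)
  methods::as(methods::as(m, "dMatrix"), "CsparseMatrix")
}

#' Parameter-vector I/O as two-column TSV
#'
#' Column 1 is the feature label (syntax fixed by [feature_labels()]),
#' column 2 the value. On read, labels are checked against the model when
#' one is supplied, and reordered to embedding order if needed.
#'
#' @param theta Numeric vector named by feature labels (unnamed vectors are
#'   labelled from `model`).
#' @param model An `"sfr_model"` (optional for reading).
#' @param path File path.
#' @export
write_parameters <- function(theta, model, path) {
  theta <- check_theta(model, theta)
  df <- data.frame(feature_label = feature_labels(model), value = theta,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path, model = NULL) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "numeric"),
                          comment.char = "")
  theta <- stats::setNames(df[[2L]], df[[1L]])
  if (!is.null(model)) {
    theta <- stats::setNames(check_theta(model, theta),
                             feature_labels(model))
  }
  theta
}

#' Sequence I/O as plain FASTA
#'
#' Sequences are handled as [Biostrings::BStringSet] so arbitrary
#' alphabets are supported.
#'
#' @param sequences Named or unnamed character vector of sequences.
#' @param path File path.
#' @return `read_fasta` returns a named character vector.
#' @export
write_fasta <- function(sequences, path) {
  ids <- names(sequences)
  if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  x <- Biostrings::BStringSet(unname(sequences))
  names(x) <- ids
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Evaluate a model on a FASTA file of sequences
#'
#' Reads parameters (TSV) and sequences (FASTA), validates every record
#' (alphabet membership and length; offending record ids are reported), and
#' writes a two-column TSV of `(id, prediction)`.
#'
#' @param model An `"sfr_model"` (or path to a JSON config).
#' @param theta_path Parameter TSV path.
#' @param fasta_path FASTA path.
#' @param out_path Output TSV path.
#' @return Invisibly, the predictions (named numeric vector).
#' @export
evaluate_file <- function(model, theta_path, fasta_path, out_path) {
  if (is.character(model)) model <- read_model_config(model)
  stopifnot(inherits(model, "sfr_model"))
  theta <- read_parameters(theta_path, model)
  seqs <- read_fasta(fasta_path)
  bad <- vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1L]]
    length(ch) != model$L || !all(ch %in% model$alphabet)
  }, logical(1))
  if (any(bad)) {
    stop("invalid sequence record(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  }
  pred <- evaluate_model(model, theta, unname(seqs))
  # fixed 12-significant-digit formatting: gauge-equivalent parameter files
  # yield byte-identical prediction files (raw doubles would differ in the
  # last couple of bits)
  df <- data.frame(id = names(seqs),
                   prediction = formatC(pred, format = "g", digits = 12),
                   stringsAsFactors = FALSE)
  utils::write.table(df, out_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(stats::setNames(pred, names(seqs)))
}

#' Deterministic random fixtures for testing
#'
#' Generates, reproducibly from a seed, a random model spec (random family
#' of position sets), a random parameter TSV for it, a random FASTA of
#' valid sequences, and a random PSCP element; files are written under
#' `dir`.
#'
#' @param kind One of `"spec"`, `"theta"`, `"fasta"`, `"pscp"`, `"all"`.
#' @param seed Integer seed.
#' @param dir Output directory (created if missing).
#' @param alphabet,L Sequence space to draw from.
#' @return Named list of generated file paths and in-memory objects.
#' @export
make_fixture <- function(kind = c("all", "spec", "theta", "fasta", "pscp"),
                         seed, dir = tempdir(),
                         alphabet = c("A", "C", "G", "T"), L = 3L) {
  kind <- match.arg(kind)
  alphabet <- as_alphabet(alphabet)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  out <- list()
  nsets <- sample(2:4, 1L)
  sets <- unique(c(list(integer(0)), lapply(seq_len(nsets), function(i)
    sort(sample(L, sample(seq_len(min(2L, L)), 1L))))))
  model <- sfr_model(alphabet, L, "one-hot", sets)
  if (kind %in% c("all", "spec")) {
    out$spec <- file.path(dir, sprintf("model_seed%d.json", seed))
    write_model_config(model, out$spec)
  }
  if (kind %in% c("all", "theta")) {
    theta <- round(stats::rnorm(model$M), 6)
    out$theta <- file.path(dir, sprintf("theta_seed%d.tsv", seed))
    write_parameters(theta, model, out$theta)
  }
  if (kind %in% c("all", "fasta")) {
    n <- 8L
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(alphabet, L, replace = TRUE), collapse = ""),
      character(1))
    names(seqs) <- sprintf("s%02d", seq_len(n))
    out$fasta <- file.path(dir, sprintf("seqs_seed%d.fasta", seed))
    write_fasta(seqs, out$fasta)
  }
  if (kind %in% c("all", "pscp")) {
    out$pscp <- random_pscp(alphabet, L)
  }
  out$model <- model
  out
}
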