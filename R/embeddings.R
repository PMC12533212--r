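#' Static word-embedding models
#'
#' Reads text-format embedding files and exposes vocabulary lookup with
#' multiword-phrase resolution and cosine similarity. Two formats are
#' supported: GloVe text (space-separated `word v1 ... vd`, no header) and
#' word2vec text (a `count dim` header line followed by the same rows).
#' Binary formats and subword OOV reconstruction are out of scope.
#'
#' @param path File path.
#' @param format `"glove_txt"` or `"word2vec_txt"`.
#' @param id Model identifier; defaults to the file stem.
#' @param metadata Free-text note (corpus, algorithm).
#'
#' @return An object of class `embedding_model`: list with `id`, `dimension`,
#'   `vectors` (numeric matrix, one row per vocabulary word), `metadata`.
#'   Duplicate vocabulary entries keep the first occurrence (a warning names
#'   the duplicates).
#' @export
read_embeddings <- function(path, format = c("glove_txt", "word2vec_txt"),
                            id = NULL, metadata = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_stereolang("stereolang_format_error",
                    sprintf("embedding file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    stop_stereolang("stereolang_content_error",
                    sprintf("embedding file %s is empty", path))
  }
  offset <- 0L
  declared <- NULL
  if (format == "word2vec_txt") {
    header <- strsplit(trimws(lines[[1L]]), "[[:space:]]+")[[1L]]
    if (length(header) != 2L || anyNA(suppressWarnings(as.integer(header)))) {
      stop_stereolang("stereolang_format_error",
                      sprintf("%s: malformed word2vec header '%s'",
                              path, lines[[1L]]))
    }
    declared <- as.integer(header)  # c(count, dim)
    offset <- 1L
    if (length(lines) - 1L != declared[[1L]]) {
      stop_stereolang(
        "stereolang_format_error",
        sprintf("%s: header declares %d rows but file has %d",
                path, declared[[1L]], length(lines) - 1L))
    }
  }
  body <- lines[(offset + 1L):length(lines)]
  parts <- strsplit(trimws(body), "[[:space:]]+")
  dims <- lengths(parts) - 1L
  dim <- if (!is.null(declared)) declared[[2L]] else dims[[1L]]
  bad <- which(dims != dim)
  if (length(bad) > 0L) {
    stop_stereolang(
      "stereolang_format_error",
      sprintf("%s: line %d has %d values, expected %d",
              path, bad[[1L]] + offset, dims[[bad[[1L]]]], dim))
  }
  words <- vapply(parts, `[[`, character(1L), 1L)
  vals <- suppressWarnings(
    vapply(parts, function(p) as.numeric(p[-1L]), numeric(dim)))
  mat <- if (dim == 1L) matrix(vals, ncol = 1L) else t(vals)
  if (anyNA(mat) || any(!is.finite(mat))) {
    stop_stereolang("stereolang_format_error",
                    sprintf("%s: non-numeric or non-finite vector entries", path))
  }
  dup <- duplicated(words)
  if (any(dup)) {
    warn(sprintf("duplicate vocabulary entries kept first: %s",
                 paste(unique(words[dup]), collapse = ", ")))
    mat <- mat[!dup, , drop = FALSE]
    words <- words[!dup]
  }
  rownames(mat) <- words
  embedding_model(id = id %||% sub("\\.[^.]+$", "", basename(path)),
                  vectors = mat, metadata = metadata)
}

#' Construct an embedding model from a word-by-dimension matrix
#'
#' @param id Model identifier.
#' @param vectors Numeric matrix with one row per word; rownames are the
#'   vocabulary.
#' @param metadata Free-text note.
#' @return An `embedding_model`.
#' @export
embedding_model <- function(id, vectors, metadata = NA_character_) {
  stopifnot(is.matrix(vectors), is.numeric(vectors),
            !is.null(rownames(vectors)))
  if (nrow(vectors) == 0L) {
    stop_stereolang("stereolang_content_error", "vocabulary is empty")
  }
  if (any(!is.finite(vectors))) {
    stop_stereolang("stereolang_content_error", "vectors must be finite")
  }
  structure(list(id = id, dimension = ncol(vectors), vectors = vectors,
                 metadata = metadata),
            class = "embedding_model")
}

#' @export
print.embedding_model <- function(x, ...) {
  cat(sprintf("<embedding_model '%s'> %d words x %d dims\n",
              x$id, nrow(x$vectors), x$dimension))
  invisible(x)
}

#' Write an embedding model to a text file
#'
#' @param model An `embedding_model`.
#' @param path Output path.
#' @param format `"glove_txt"` or `"word2vec_txt"`.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(model, path,
                             format = c("glove_txt", "word2vec_txt")) {
  stopifnot(inherits(model, "embedding_model"))
  format <- match.arg(format)
  rows <- paste(rownames(model$vectors),
                apply(model$vectors, 1L, paste, collapse = " "))
  if (format == "word2vec_txt") {
    rows <- c(paste(nrow(model$vectors), model$dimension), rows)
  }
  writeLines(rows, path)
  invisible(path)
}

#' Resolve a lexeme to an embedding vector
#'
#' Single-token lexemes are exact vocabulary lookups. Multiword lexemes
#' (e.g. "artificial intelligence") resolve to the unweighted mean of their
#' component-token vectors; every component must be in vocabulary.
#'
#' @param model An `embedding_model`.
#' @param lexeme A normalized lexeme (see [normalize_lexeme()]).
#' @return A numeric vector of length `model$dimension`.
#' @export
resolve_vector <- function(model, lexeme) {
  stopifnot(inherits(model, "embedding_model"), is.character(lexeme),
            length(lexeme) == 1L)
  tokens <- strsplit(lexeme, " ", fixed = TRUE)[[1L]]
  missing <- setdiff(tokens, rownames(model$vectors))
  if (length(missing) > 0L) {
    stop_stereolang(
      "stereolang_oov_error",
      sprintf("token(s) out of vocabulary in model '%s': %s",
              model$id, paste(missing, collapse = ", ")),
      tokens = missing)
  }
  if (length(tokens) == 1L) {
    model$vectors[tokens, ]
  } else {
    colMeans(model$vectors[tokens, , drop = FALSE])
  }
}

#' Cosine similarity
#'
#' `u . v / (|u| |v|)`; symmetric and invariant to positive rescaling of
#' either argument. Zero vectors are rejected.
#'
#' @param u,v Numeric vectors of equal length.
#' @return A scalar in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  stopifnot(is.numeric(u), is.numeric(v), length(u) == length(v))
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop_stereolang("stereolang_degenerate_error",
                    "cosine similarity is undefined for a zero vector")
  }
  sum(u * v) / (nu * nv)
}
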