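#' Word lists (lexicons) and attribute contrasts
#'
#' A lexicon is a named, polarity-labeled list of lexemes playing either a
#' *target* role (the category under study, e.g. AI-related terms or a
#' demographic group) or an *attribute* role (one pole of a stereotype
#' dimension, e.g. high-competence words). Lexemes are normalized by
#' case-folding and collapsing internal whitespace; multiword lexemes
#' ("artificial intelligence") are kept as single entries and resolved to
#' vectors downstream.
#'
#' @param name Identifier for the word list.
#' @param words Character vector of lexemes (may be multiword); normalized
#'   and checked for duplicates.
#' @param role `"target"` or `"attribute"`.
#' @param polarity Optional: `"high"`, `"low"`, `"advantaged"`,
#'   `"disadvantaged"` or `"none"`.
#' @param dimension Optional stereotype dimension label, e.g. `"competence"`,
#'   `"warmth"`, `"gender"`, `"age"`, `"class"`, `"race"`, `"occupation"`.
#' @param source Free-text provenance of the list.
#'
#' @return An object of class `lexicon`: a list with fields `name`, `role`,
#'   `polarity`, `dimension`, `words`, `source`.
#' @export
#'
#' @examples
#' lexicon("ai_terms", c("robot", "artificial intelligence"), role = "target")
lexicon <- function(name, words, role = c("target", "attribute"),
                    polarity = "none", dimension = NA_character_,
                    source = NA_character_) {
  role <- match.arg(role)
  polarity <- match.arg(polarity,
                        c("none", "high", "low", "advantaged", "disadvantaged"))
  if (!is.character(words) || length(words) == 0L) {
    stop_stereolang("stereolang_content_error",
                    sprintf("lexicon '%s' must contain at least one word", name))
  }
  norm <- normalize_lexeme(words)
  dup <- unique(norm[duplicated(norm)])
  if (length(dup) > 0L) {
    stop_stereolang(
      "stereolang_content_error",
      sprintf("lexicon '%s' contains duplicate lexemes after normalization: %s",
              name, paste(dup, collapse = ", ")))
  }
  structure(
    list(name = name, role = role, polarity = polarity,
         dimension = dimension, words = norm, source = source),
    class = "lexicon")
}

#' Normalize lexemes
#'
#' Case-folds and collapses runs of internal whitespace to a single space;
#' leading/trailing whitespace is stripped. Idempotent.
#'
#' @param x Character vector.
#' @return Normalized character vector of the same length.
#' @export
normalize_lexeme <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

#' @export
print.lexicon <- function(x, ...) {
  cat(sprintf("<lexicon '%s'> role=%s polarity=%s dimension=%s (%d lexemes)\n",
              x$name, x$role, x$polarity, x$dimension, length(x$words)))
  cat("  ", paste(head(x$words, 8L), collapse = ", "),
      if (length(x$words) > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
format.lexicon <- function(x, ...) {
  sprintf("<lexicon '%s': %d lexemes>", x$name, length(x$words))
}

lexicon_fields <- c("word", "role", "polarity", "dimension", "source")

#' Read a lexicon from CSV or JSON
#'
#' CSV files need columns `word,role,polarity,dimension,source` (one row per
#' lexeme; role/polarity/dimension/source are taken from the first row). JSON
#' files hold one object with keys `name`, `role`, `polarity`, `dimension`,
#' `source`, `words`. File order of words is preserved.
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; default inferred from the extension.
#' @param name Lexicon name; defaults to the file stem for CSV (JSON carries
#'   its own `name`).
#' @return A [lexicon].
#' @export
read_lexicon <- function(path, format = c("auto", "csv", "json"), name = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) {
    stop_stereolang("stereolang_schema_error",
                    sprintf("lexicon file not found: %s", path))
  }
  if (format == "csv") {
    df <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
    missing <- setdiff(lexicon_fields, names(df))
    if (length(missing) > 0L) {
      stop_stereolang("stereolang_schema_error",
                      sprintf("lexicon CSV %s is missing columns: %s",
                              path, paste(missing, collapse = ", ")))
    }
    if (nrow(df) == 0L) {
      stop_stereolang("stereolang_content_error",
                      sprintf("lexicon CSV %s has no rows", path))
    }
    lexicon(name = name %||% sub("\\.[^.]+$", "", basename(path)),
            words = df$word,
            role = df$role[[1L]],
            polarity = df$polarity[[1L]] %||% "none",
            dimension = df$dimension[[1L]],
            source = df$source[[1L]])
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    needed <- c("name", "role", "words")
    missing <- setdiff(needed, names(obj))
    if (length(missing) > 0L) {
      stop_stereolang("stereolang_schema_error",
                      sprintf("lexicon JSON %s is missing keys: %s",
                              path, paste(missing, collapse = ", ")))
    }
    lexicon(name = obj$name, words = obj$words, role = obj$role,
            polarity = obj$polarity %||% "none",
            dimension = obj$dimension %||% NA_character_,
            source = obj$source %||% NA_character_)
  }
}

#' Write a lexicon to CSV or JSON
#'
#' Inverse of [read_lexicon()]: `read_lexicon(write_lexicon(x, p))` returns a
#' lexicon equal to `x`.
#'
#' @param x A [lexicon].
#' @param path Output file path.
#' @param format `"csv"` or `"json"`; default inferred from the extension.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(x, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(x, "lexicon"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    df <- tibble(word = x$words, role = x$role, polarity = x$polarity,
                 dimension = x$dimension, source = x$source)
    readr::write_csv(df, path)
  } else {
    jsonlite::write_json(
      list(name = x$name, role = x$role, polarity = x$polarity,
           dimension = x$dimension, source = x$source, words = x$words),
      path, auto_unbox = TRUE, null = "null")
  }
  invisible(path)
}

#' Build a validated attribute (or group) contrast
#'
#' Pairs a high-pole lexicon with a low-pole lexicon of the same role and
#' dimension (e.g. high- vs low-competence attributes, or an advantaged vs
#' disadvantaged group). The two word sets must be disjoint.
#'
#' @param high,low [lexicon]s for the two poles.
#' @param label Contrast label (defaults to the shared dimension).
#' @return An object of class `contrast_pair` with fields `high`, `low`,
#'   `label`.
#' @export
make_contrast <- function(high, low, label = NULL) {
  stopifnot(inherits(high, "lexicon"), inherits(low, "lexicon"))
  if (high$role != low$role) {
    stop_stereolang("stereolang_content_error",
                    "contrast poles must share the same role")
  }
  if (!identical(high$dimension, low$dimension)) {
    stop_stereolang("stereolang_content_error",
                    "contrast poles must share the same dimension")
  }
  overlap <- intersect(high$words, low$words)
  if (length(overlap) > 0L) {
    stop_stereolang(
      "stereolang_content_error",
      sprintf("contrast poles overlap: %s", paste(overlap, collapse = ", ")))
  }
  label <- label %||% high$dimension
  if (is.null(label) || is.na(label)) label <- "contrast"
  structure(list(high = high, low = low, label = label),
            class = "contrast_pair")
}

#' Mirror a contrast pair
#'
#' Exchanges the high and low poles; `mirror_contrast(mirror_contrast(p))`
#' equals `p`. Association scores and effect estimates are antisymmetric
#' under this operation.
#'
#' @param pair A `contrast_pair`.
#' @return The mirrored `contrast_pair`.
#' @export
mirror_contrast <- function(pair) {
  stopifnot(inherits(pair, "contrast_pair"))
  structure(list(high = pair$low, low = pair$high, label = pair$label),
            class = "contrast_pair")
}

#' @export
print.contrast_pair <- function(x, ...) {
  cat(sprintf("<contrast '%s'> high=%s (%d) vs low=%s (%d)\n", x$label,
              x$high$name, length(x$high$words),
              x$low$name, length(x$low$words)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
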