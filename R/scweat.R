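#' Single-Category Word Embedding Association Test (SC-WEAT)
#'
#' For one target word `w` and an attribute contrast (high vs low pole), the
#' association score is the difference of mean cosine similarities:
#'
#'   score(w) = mean_a cos(w, a) - mean_b cos(w, b)
#'
#' over the high-pole attribute words `a` and low-pole words `b`. Positive
#' scores mean the target sits semantically closer to the high pole.
#'
#' @param model An `embedding_model`.
#' @param target A single lexeme (normalized; may be multiword).
#' @param pair A `contrast_pair` of attribute lexicons.
#' @param dictionary_id Label for the attribute dictionary; defaults to the
#'   high-pole lexicon's `source` (or the contrast label).
#' @param oov Out-of-vocabulary policy for *attribute* words: `"error"`
#'   (default) fails on the first unresolvable lexeme; `"skip"` drops it and
#'   records the reduced attribute counts. The target itself must always
#'   resolve.
#'
#' @return A one-row tibble (an association record): `target`, `contrast`,
#'   `model_id`, `dictionary_id`, `score`, `n_high`, `n_low`.
#' @export
#'
#' @examples
#' m <- embedding_model("toy", matrix(c(1, 0, 1, 0, 0, 1), 3, 2, byrow = TRUE,
#'                      dimnames = list(c("robot", "smart", "dumb"), NULL)))
#' pair <- make_contrast(lexicon("hi", "smart", "attribute", "high"),
#'                       lexicon("lo", "dumb", "attribute", "low"), "competence")
#' association_score(m, "robot", pair)
association_score <- function(model, target, pair,
                              dictionary_id = NULL, oov = c("error", "skip")) {
  oov <- match.arg(oov)
  stopifnot(inherits(pair, "contrast_pair"))
  dictionary_id <- dictionary_id %||% pair$high$source %||% pair$label
  w <- resolve_vector(model, target)
  hi <- resolve_pole(model, pair$high$words, oov)
  lo <- resolve_pole(model, pair$low$words, oov)
  if (length(hi) == 0L || length(lo) == 0L) {
    stop_stereolang("stereolang_degenerate_error",
                    "no resolvable attribute word on one side of the contrast")
  }
  score <- mean(vapply(hi, cosine_similarity, numeric(1L), u = w)) -
    mean(vapply(lo, cosine_similarity, numeric(1L), u = w))
  tibble(target = target, contrast = pair$label, model_id = model$id,
         dictionary_id = dictionary_id, score = score,
         n_high = length(hi), n_low = length(lo))
}

# Resolve a pole's lexemes to a list of vectors, honouring the OOV policy.
resolve_pole <- function(model, words, oov) {
  out <- list()
  for (w in words) {
    v <- tryCatch(resolve_vector(model, w), stereolang_oov_error = function(e) {
      if (oov == "error") stop(e)
      warn(sprintf("skipping OOV attribute lexeme '%s' in model '%s'",
                   w, model$id))
      NULL
    })
    if (!is.null(v)) out[[w]] <- v
  }
  out
}

#' Association scores for a whole target lexicon
#'
#' @param model An `embedding_model`.
#' @param targets A target [lexicon].
#' @inheritParams association_score
#' @param oov_targets Policy for unresolvable target lexemes: `"error"` or
#'   `"skip"` (skip-and-log; the record is simply absent).
#' @return A tibble of association records, one row per resolvable target.
#' @export
association_scores <- function(model, targets, pair, dictionary_id = NULL,
                               oov = c("error", "skip"),
                               oov_targets = c("error", "skip")) {
  oov <- match.arg(oov)
  oov_targets <- match.arg(oov_targets)
  stopifnot(inherits(targets, "lexicon"))
  rows <- lapply(targets$words, function(tw) {
    tryCatch(
      association_score(model, tw, pair, dictionary_id = dictionary_id,
                        oov = oov),
      stereolang_oov_error = function(e) {
        if (oov_targets == "error") stop(e)
        warn(sprintf("skipping OOV target lexeme '%s'", tw))
        NULL
      })
  })
  dplyr::bind_rows(rows)
}

#' Classic SC-WEAT effect size
#'
#' The standardized mean association over target words:
#' `d = mean(score) / sd(score)`, the single-category analogue of the WEAT
#' effect size. The standard error is that of the mean of the standardized
#' scores, `1 / sqrt(n)`; the p-value is from the one-sample t statistic
#' `d * sqrt(n)` on `n - 1` degrees of freedom.
#'
#' @param records A tibble of association records for one model and
#'   dictionary (from [association_scores()]), with at least two distinct
#'   scores.
#' @return An [effect_estimate()] row.
#' @export
scweat_effect <- function(records) {
  scores <- records$score
  if (length(scores) < 2L) {
    stop_stereolang("stereolang_degenerate_error",
                    "need at least two target-word scores")
  }
  s <- sd(scores)
  if (s == 0) {
    stop_stereolang("stereolang_degenerate_error",
                    "zero variance across target scores: effect undefined")
  }
  n <- length(scores)
  d <- mean(scores) / s
  tval <- d * sqrt(n)
  effect_estimate(estimate = d, se = 1 / sqrt(n),
                  p = 2 * pt(-abs(tval), df = n - 1L),
                  n_obs = n, method = "scweat",
                  dimension = records$contrast[[1L]])
}

#' Permutation p-value for an SC-WEAT association
#'
#' Tests the observed mean association against the null distribution
#' obtained by re-partitioning the pooled attribute words into high/low sets
#' of the original sizes. The p-value is the fraction of partitions whose
#' mean association is at least the observed one (one-sided). Exhaustive
#' mode enumerates all `choose(n_high + n_low, n_high)` partitions and
#' reports the exact fraction; Monte-Carlo mode samples `n_perm` partitions
#' and applies add-one smoothing `(k + 1) / (n_perm + 1)`.
#'
#' @param model An `embedding_model`.
#' @param targets A target [lexicon].
#' @param pair A `contrast_pair`.
#' @param n_perm Number of sampled partitions, or `"exhaustive"`.
#' @param seed Integer seed (required for Monte-Carlo mode).
#' @param oov OOV policy passed to the similarity computation.
#' @return A p-value in `(0, 1]`.
#' @export
permutation_pvalue <- function(model, targets, pair, n_perm = 10000L,
                               seed = NULL, oov = c("error", "skip")) {
  oov <- match.arg(oov)
  sims <- similarity_matrix(model, targets, pair, oov)
  n_high <- sum(sims$polarity == 1L)
  n_total <- length(sims$polarity)
  if (n_total < 2L || n_high == 0L || n_high == n_total) {
    stop_stereolang("stereolang_degenerate_error",
                    "need at least one attribute word on each side")
  }
  # mean over targets of (mean high sim - mean low sim) for an index set
  stat_for <- function(high_idx) {
    lo <- setdiff(seq_len(n_total), high_idx)
    mean(rowMeans(sims$mat[, high_idx, drop = FALSE])) -
      mean(rowMeans(sims$mat[, lo, drop = FALSE]))
  }
  observed <- stat_for(seq_len(n_high))
  if (identical(n_perm, "exhaustive")) {
    combos <- utils::combn(n_total, n_high, simplify = FALSE)
    stats <- vapply(combos, stat_for, numeric(1L))
    mean(stats >= observed - 1e-12)
  } else {
    stopifnot(is.numeric(n_perm), n_perm >= 1L)
    if (is.null(seed)) {
      stop_stereolang("stereolang_schema_error",
                      "Monte-Carlo permutation requires a seed")
    }
    set.seed(seed)
    k <- sum(vapply(seq_len(n_perm), function(i) {
      stat_for(sample.int(n_total, n_high))
    }, numeric(1L)) >= observed - 1e-12)
    (k + 1) / (n_perm + 1)
  }
}

# targets x attributes cosine-similarity matrix; polarity marks high columns.
similarity_matrix <- function(model, targets, pair, oov = "error") {
  hi <- resolve_pole(model, pair$high$words, oov)
  lo <- resolve_pole(model, pair$low$words, oov)
  tv <- lapply(targets$words, resolve_vector, model = model)
  att <- c(hi, lo)
  mat <- vapply(att, function(a) {
    vapply(tv, cosine_similarity, numeric(1L), v = a)
  }, numeric(length(tv)))
  mat <- matrix(mat, nrow = length(tv))
  list(mat = mat,
       polarity = c(rep(1L, length(hi)), rep(0L, length(lo))),
       attribute = c(names(hi), names(lo)),
       targets = targets$words)
}

#' Long-format target-by-attribute similarities
#'
#' One row per (target word, attribute word) cosine similarity, tagged with
#' model, dictionary and attribute polarity. This is the observation unit of
#' [pooled_regression()].
#'
#' @inheritParams association_score
#' @param targets A target [lexicon].
#' @return A tibble: `target`, `attribute`, `polarity` (1 = high pole),
#'   `similarity`, `contrast`, `model_id`, `dictionary_id`.
#' @export
similarity_long <- function(model, targets, pair, dictionary_id = NULL,
                            oov = c("error", "skip")) {
  oov <- match.arg(oov)
  dictionary_id <- dictionary_id %||% pair$high$source %||% pair$label
  sims <- similarity_matrix(model, targets, pair, oov)
  tibble(
    target = rep(sims$targets, times = ncol(sims$mat)),
    attribute = rep(sims$attribute, each = nrow(sims$mat)),
    polarity = rep(sims$polarity, each = nrow(sims$mat)),
    similarity = as.vector(sims$mat),
    contrast = pair$label,
    model_id = model$id,
    dictionary_id = dictionary_id)
}

#' Pooled standardized regression across embedding models
#'
#' The pooled estimator regresses per-(target, attribute) cosine
#' similarities on the attribute polarity indicator (high = 1, low = 0),
#' after scaling similarities to unit standard deviation within each
#' model-by-dictionary cell. With this coding and scaling the OLS slope is a
#' standardized mean difference, directly interpretable as Cohen's *d*.
#'
#' @param sims A similarity tibble from [similarity_long()], possibly
#'   row-bound across several models and dictionaries.
#' @return An [effect_estimate()] row (slope, SE, 95% CI, two-sided p).
#' @export
pooled_regression <- function(sims) {
  stopifnot(all(c("similarity", "polarity", "model_id", "dictionary_id")
                %in% names(sims)))
  if (length(unique(sims$polarity)) < 2L) {
    stop_stereolang("stereolang_design_error",
                    "both attribute polarities must be represented")
  }
  sims <- dplyr::mutate(
    dplyr::group_by(sims, .data$model_id, .data$dictionary_id),
    sim_std = .data$similarity / sd(.data$similarity))
  sims <- dplyr::ungroup(sims)
  if (anyNA(sims$sim_std) || any(!is.finite(sims$sim_std))) {
    stop_stereolang("stereolang_degenerate_error",
                    "zero similarity variance within a model-dictionary cell")
  }
  fit <- lm(sim_std ~ polarity, data = sims)
  sm <- summary(fit)$coefficients
  effect_estimate(estimate = sm["polarity", "Estimate"],
                  se = sm["polarity", "Std. Error"],
                  p = sm["polarity", "Pr(>|t|)"],
                  n_obs = nrow(sims), method = "scweat_pooled",
                  dimension = if ("contrast" %in% names(sims))
                    sims$contrast[[1L]] else NA_character_)
}
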