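#' Fill-Mask Association Test (FMAT)
#'
#' FMAT probes a masked language model with propositional queries such as
#' "The \[MASK\] is \{ATTRIB\}", where the mask is to be filled by a target
#' word (e.g. an AI term) and \{ATTRIB\} alternates between a matched pair of
#' attribute words (e.g. "warm" / "cold"). The log-probability contrast
#' `log p(target | high context) - log p(target | low context)` measures the
#' target's semantic alignment with the high pole.
#'
#' `build_queries()` renders the Cartesian product of templates, target
#' words and positionally matched attribute pairs into individual queries
#' (two per pair: the high and the low variant), deterministically ordered.
#'
#' @param templates Character vector of templates, each containing exactly
#'   one `[MASK]` slot and one `{ATTRIB}` slot.
#' @param targets A target [lexicon].
#' @param pair A `contrast_pair` of attribute lexicons whose word lists are
#'   matched positionally (word *i* of the high pole pairs with word *i* of
#'   the low pole), so both poles must have equal length.
#'
#' @return A tibble with one row per rendered query: `query_id`, `pair_id`,
#'   `template`, `target_word`, `attrib_word`, `polarity` (`"high"` /
#'   `"low"`), `context` (the template with `{ATTRIB}` substituted and the
#'   `[MASK]` slot left in place).
#' @export
#'
#' @examples
#' pair <- make_contrast(
#'   lexicon("hi", "warm", "attribute", "high", "warmth"),
#'   lexicon("lo", "cold", "attribute", "low", "warmth"))
#' build_queries("The [MASK] is {ATTRIB}.",
#'               lexicon("ai", "robot", "target"), pair)
build_queries <- function(templates, targets, pair) {
  stopifnot(is.character(templates), length(templates) >= 1L,
            inherits(targets, "lexicon"), inherits(pair, "contrast_pair"))
  for (tpl in templates) {
    for (slot in c("[MASK]", "{ATTRIB}")) {
      if (!grepl(slot, tpl, fixed = TRUE)) {
        stop_stereolang("stereolang_template_error",
                        sprintf("template '%s' is missing the %s slot",
                                tpl, slot))
      }
    }
  }
  nh <- length(pair$high$words)
  if (nh != length(pair$low$words)) {
    stop_stereolang("stereolang_content_error",
                    "attribute poles must have equal length for pairing")
  }
  grid <- tidyr::expand_grid(
    template_i = seq_along(templates),
    target_word = targets$words,
    pair_i = seq_len(nh),
    polarity = c("high", "low"))
  grid <- dplyr::mutate(
    grid,
    template = templates[.data$template_i],
    attrib_word = ifelse(.data$polarity == "high",
                         pair$high$words[.data$pair_i],
                         pair$low$words[.data$pair_i]),
    pair_id = sprintf("t%02d.%s.p%02d", .data$template_i,
                      gsub(" ", "_", .data$target_word), .data$pair_i),
    query_id = paste0(.data$pair_id, ".", .data$polarity),
    context = mapply(function(tpl, att) sub("{ATTRIB}", att, tpl, fixed = TRUE),
                     .data$template, .data$attrib_word, USE.NAMES = FALSE))
  dplyr::select(grid, "query_id", "pair_id", "template", "target_word",
                "attrib_word", "polarity", "context")
}

#' Mask adapters: providers of fill-mask probabilities
#'
#' An adapter is any object answering `p(token at [MASK] | context)`. The
#' shipped implementation is a deterministic lookup table keyed by
#' `(context, token)`, suitable for tests and for replaying logged model
#' output; a live masked-LM backend satisfying the same contract can be
#' injected instead.
#'
#' @param table A data frame with columns `context`, `token`, `prob`
#'   (probabilities in `(0, 1]`).
#' @param model_id Identifier reported in observations.
#' @return An object of class `mask_adapter`.
#' @export
mock_mask_adapter <- function(table, model_id = "mock") {
  table <- as_tibble(table)
  stopifnot(all(c("context", "token", "prob") %in% names(table)),
            all(table$prob > 0), all(table$prob <= 1))
  key <- paste0(table$context, "\r", table$token)
  if (anyDuplicated(key)) {
    stop_stereolang("stereolang_content_error",
                    "duplicate (context, token) entries in adapter table")
  }
  structure(list(probs = setNames(table$prob, key), model_id = model_id),
            class = "mask_adapter")
}

#' Score one query with a mask adapter
#'
#' @param adapter A `mask_adapter` (see [mock_mask_adapter()]).
#' @param query One row of a [build_queries()] tibble (or any list with
#'   `context` and `target_word`).
#' @return The natural-log probability of the target word at the mask.
#' @export
score_mask <- function(adapter, query) {
  stopifnot(inherits(adapter, "mask_adapter"))
  key <- paste0(query$context, "\r", query$target_word)
  p <- adapter$probs[key]
  if (is.na(p)) {
    stop_stereolang(
      "stereolang_tokenization_error",
      sprintf("adapter '%s' cannot score token '%s' in context '%s'",
              adapter$model_id, query$target_word, query$context))
  }
  log(unname(p))
}

#' Run a query set through an adapter, collapsing high/low variants
#'
#' Queries whose target the adapter cannot tokenize are skipped with a
#' warning (both variants of the affected pair are dropped).
#'
#' @param adapter A `mask_adapter`.
#' @param queries A [build_queries()] tibble.
#' @return A tibble of fill-mask observations: `query_id` (the pair id),
#'   `model_id`, `target_word`, `attrib_high_word`, `attrib_low_word`,
#'   `logp_high`, `logp_low`, `contrast = logp_high - logp_low`.
#' @export
fmat_observe <- function(adapter, queries) {
  scored <- queries
  scored$logp <- vapply(seq_len(nrow(queries)), function(i) {
    tryCatch(score_mask(adapter, queries[i, ]),
             stereolang_tokenization_error = function(e) {
               warn(conditionMessage(e))
               NA_real_
             })
  }, numeric(1L))
  wide <- tidyr::pivot_wider(
    dplyr::select(scored, "pair_id", "target_word", "polarity",
                  "attrib_word", "logp"),
    names_from = "polarity", values_from = c("attrib_word", "logp"))
  wide <- dplyr::filter(wide, !is.na(.data$logp_high), !is.na(.data$logp_low))
  tibble(query_id = wide$pair_id,
         model_id = adapter$model_id,
         target_word = wide$target_word,
         attrib_high_word = wide$attrib_word_high,
         attrib_low_word = wide$attrib_word_low,
         logp_high = wide$logp_high,
         logp_low = wide$logp_low,
         contrast = wide$logp_high - wide$logp_low)
}

#' FMAT standardized association estimate
#'
#' Per-pair log-probability contrasts are scaled to unit standard deviation
#' within each model, then pooled: the estimate is the intercept of an OLS
#' fit of the standardized contrast on a constant (equivalently its mean),
#' a Cohen's-d-equivalent standardized contrast comparable to the slope of
#' [pooled_regression()], with its OLS standard error, 95% CI and two-sided
#' p-value.
#'
#' @param observations A tibble from [fmat_observe()], possibly row-bound
#'   across models.
#' @return An [effect_estimate()] row.
#' @export
fmat_association <- function(observations) {
  stopifnot(all(c("contrast", "model_id", "logp_high", "logp_low")
                %in% names(observations)))
  if (nrow(observations) < 2L) {
    stop_stereolang("stereolang_degenerate_error",
                    "need at least two fill-mask observations")
  }
  obs <- dplyr::mutate(dplyr::group_by(observations, .data$model_id),
                       contrast_std = .data$contrast / sd(.data$contrast))
  obs <- dplyr::ungroup(obs)
  if (anyNA(obs$contrast_std) || any(!is.finite(obs$contrast_std))) {
    stop_stereolang("stereolang_degenerate_error",
                    "all contrasts identical within a model: effect undefined")
  }
  fit <- lm(contrast_std ~ 1, data = obs)
  sm <- summary(fit)$coefficients
  effect_estimate(estimate = sm["(Intercept)", "Estimate"],
                  se = sm["(Intercept)", "Std. Error"],
                  p = sm["(Intercept)", "Pr(>|t|)"],
                  n_obs = nrow(obs), method = "fmat")
}
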