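#' Occupation probe of a generative language model
#'
#' The probe asks a generative model which occupations benefit from AI and
#' which are replaced by it, using two prompt families ("The occupation that
#' is more likely to benefit from Artificial Intelligence is {MASK}" vs
#' "The job that is most likely to be replaced by Artificial Intelligence is
#' {MASK}"). Each task embeds a random batch of candidate occupations; the
#' provider returns its top-k completions with probabilities, from which
#' per-occupation probability samples are accumulated and summarized as the
#' log-ratio score
#'
#'   q(x) = ln( mean_i p(x | benefit_i) / mean_j p(x | replacement_j) )
#'
#' with q > 0 meaning the occupation is associated more with benefiting
#' from AI than with being replaced by it.
#'
#' @param benefit_templates,replacement_templates Character vectors of
#'   prompt templates containing a `{MASK}` slot.
#' @param occupations Character vector of occupation lexemes.
#' @param batch_size Occupations embedded per prompt (default 20).
#' @param min_appearances Minimum number of scheduled appearances of every
#'   occupation under each prompt family (default 100).
#' @param seed Integer seed driving batch sampling.
#' @return An object of class `prompt_set`.
#' @export
prompt_set <- function(benefit_templates, replacement_templates, occupations,
                       batch_size = 20L, min_appearances = 100L, seed = 1L) {
  stopifnot(is.character(benefit_templates), length(benefit_templates) >= 1L,
            is.character(replacement_templates),
            length(replacement_templates) >= 1L,
            is.character(occupations), length(occupations) >= 1L)
  if (batch_size > length(occupations)) {
    stop_stereolang("stereolang_content_error",
                    "batch_size cannot exceed the number of occupations")
  }
  structure(list(benefit_templates = benefit_templates,
                 replacement_templates = replacement_templates,
                 occupations = normalize_lexeme(occupations),
                 batch_size = as.integer(batch_size),
                 min_appearances = as.integer(min_appearances),
                 seed = as.integer(seed)),
            class = "prompt_set")
}

#' Build the randomized task schedule for a prompt set
#'
#' Draws seeded batches of `batch_size` occupations (without replacement
#' within a batch), cycling through the family's templates, until every
#' occupation has at least `min_appearances` scheduled appearances under
#' each family. Deterministic for a fixed seed.
#'
#' @param ps A [prompt_set()].
#' @param max_iter Safety cap on batches per family before an
#'   iteration-cap error is raised.
#' @return A tibble of tasks: `task_id`, `family` (`"benefit"` /
#'   `"replacement"`), `template`, `candidates` (list-column of occupation
#'   batches).
#' @export
make_batches <- function(ps, max_iter = NULL) {
  stopifnot(inherits(ps, "prompt_set"))
  n_occ <- length(ps$occupations)
  # expected batches needed, with generous headroom for sampling variation
  need <- ceiling(ps$min_appearances * n_occ / ps$batch_size)
  max_iter <- max_iter %||% max(50L, 10L * need)
  set.seed(ps$seed)
  schedule_family <- function(family, templates) {
    counts <- setNames(integer(n_occ), ps$occupations)
    batches <- vector("list", max_iter)
    i <- 0L
    while (any(counts < ps$min_appearances)) {
      i <- i + 1L
      if (i > max_iter) {
        stop_stereolang(
          "stereolang_iteration_cap_error",
          sprintf("family '%s' did not reach min_appearances within %d batches",
                  family, max_iter))
      }
      cand <- sample(ps$occupations, ps$batch_size)
      counts[cand] <- counts[cand] + 1L
      batches[[i]] <- cand
    }
    tibble(task_id = sprintf("%s_%04d", family, seq_len(i)),
           family = family,
           template = rep_len(templates, i),
           candidates = batches[seq_len(i)])
  }
  dplyr::bind_rows(
    schedule_family("benefit", ps$benefit_templates),
    schedule_family("replacement", ps$replacement_templates))
}

#' Deterministic mock provider of top-k occupation probabilities
#'
#' Emulates a generative-LM endpoint that returns the k most probable
#' completions with their probabilities. The mock holds a fixed
#' `(family, occupation) -> probability` table; for each task it reports
#' the candidates present in the table, truncated to the `top_k` most
#' probable, so low-probability candidates genuinely fall out of the
#' readout as they do against a live endpoint.
#'
#' @param table Data frame with columns `family`, `occupation`, `prob`
#'   (probabilities in `(0, 1]`).
#' @param top_k Size of the returned completion list (default 20).
#' @param model_id Identifier for logs.
#' @return An object of class `llm_provider`.
#' @export
mock_llm_provider <- function(table, top_k = 20L, model_id = "mock") {
  table <- as_tibble(table)
  stopifnot(all(c("family", "occupation", "prob") %in% names(table)),
            all(table$prob > 0), all(table$prob <= 1))
  structure(list(table = table, top_k = as.integer(top_k),
                 model_id = model_id),
            class = c("llm_provider_mock", "llm_provider"))
}

#' Query a provider with one task
#'
#' @param provider An `llm_provider`.
#' @param task One row of a [make_batches()] schedule (list with `family`,
#'   `template`, `candidates`).
#' @return A named numeric vector of completion probabilities (at most
#'   `top_k` entries).
#' @export
query_provider <- function(provider, task) UseMethod("query_provider")

#' @export
query_provider.llm_provider_mock <- function(provider, task) {
  cand <- task$candidates[[1L]] %||% task$candidates
  rows <- provider$table[provider$table$family == task$family &
                           provider$table$occupation %in% cand, ]
  probs <- setNames(rows$prob, rows$occupation)
  probs <- sort(probs, decreasing = TRUE)
  head(probs, provider$top_k)
}

#' Accumulate per-occupation probability samples over a task schedule
#'
#' For every task, candidates found in the provider's top-k completion list
#' contribute one probability observation to the matching family; absent
#' candidates contribute nothing (missingness, not zeros). Occupations with
#' no observation in either family are dropped with a warning.
#'
#' @param provider An `llm_provider`.
#' @param tasks A [make_batches()] schedule.
#' @param prestige Optional named numeric vector of occupational prestige
#'   values to attach (`NA` for occupations without a rating).
#' @return A tibble of occupation probes: `occupation`, `prestige`,
#'   `p_benefit` and `p_replacement` (list-columns), `n1`, `n2`.
#' @export
collect_probabilities <- function(provider, tasks, prestige = NULL) {
  stopifnot(inherits(provider, "llm_provider"))
  occ <- sort(unique(unlist(tasks$candidates)))
  acc <- list(benefit = setNames(vector("list", length(occ)), occ),
              replacement = setNames(vector("list", length(occ)), occ))
  for (i in seq_len(nrow(tasks))) {
    task <- tasks[i, ]
    probs <- query_provider(provider, task)
    hits <- intersect(task$candidates[[1L]], names(probs))
    for (x in hits) {
      acc[[task$family]][[x]] <- c(acc[[task$family]][[x]], unname(probs[[x]]))
    }
  }
  n1 <- lengths(acc$benefit)
  n2 <- lengths(acc$replacement)
  empty <- occ[n1 == 0L & n2 == 0L]
  if (length(empty) > 0L) {
    warn(sprintf("occupations never observed in any top-k readout: %s",
                 paste(empty, collapse = ", ")))
  }
  keep <- !(occ %in% empty)
  tibble(
    occupation = occ[keep],
    prestige = if (is.null(prestige)) NA_real_
               else unname(prestige[occ[keep]]),
    p_benefit = unname(acc$benefit[keep]),
    p_replacement = unname(acc$replacement[keep]),
    n1 = unname(n1[keep]),
    n2 = unname(n2[keep]))
}

#' Log-ratio benefit-versus-replacement score
#'
#' `q = ln(mean(p_benefit) / mean(p_replacement))`, the average-probability
#' log ratio. Positive q: the occupation is associated more with benefiting
#' from AI than with replacement. Invariant under a common rescaling of all
#' probabilities and exactly antisymmetric under exchanging the two
#' families.
#'
#' @param p_benefit,p_replacement Numeric vectors of probability samples
#'   from the two prompt families (each non-empty).
#' @return The scalar q score.
#' @export
q_score <- function(p_benefit, p_replacement) {
  if (length(p_benefit) < 1L || length(p_replacement) < 1L) {
    stop_stereolang("stereolang_insufficient_data_error",
                    "both prompt families need at least one observation")
  }
  mb <- mean(p_benefit)
  mr <- mean(p_replacement)
  if (mr <= 0) {
    stop_stereolang("stereolang_degenerate_error",
                    "mean replacement probability must be positive")
  }
  log(mb / mr)
}

#' Attach q scores to a probe table
#'
#' Probes missing observations in either family are dropped with a warning
#' (their q is undefined).
#'
#' @param probes A tibble from [collect_probabilities()].
#' @return The tibble with a numeric `q` column, restricted to scorable
#'   occupations.
#' @export
score_probes <- function(probes) {
  ok <- probes$n1 >= 1L & probes$n2 >= 1L
  if (any(!ok)) {
    warn(sprintf("dropping occupations without both families observed: %s",
                 paste(probes$occupation[!ok], collapse = ", ")))
  }
  probes <- probes[ok, ]
  probes$q <- vapply(seq_len(nrow(probes)), function(i) {
    q_score(probes$p_benefit[[i]], probes$p_replacement[[i]])
  }, numeric(1L))
  probes
}

#' One-sample summary of q scores
#'
#' One-sample t-test of the mean q against zero, with Cohen's
#' `d = mean / sd` and a normal-approximation 95% CI for d using
#' `SE(d) = sqrt(1/n + d^2 / (2n))`. Either raw scores or printed summary
#' moments (`mean`, `sd`, `n`) may be supplied.
#'
#' @param q Numeric vector of q scores (optional if moments are given).
#' @param mean,sd,n Summary moments, used when `q` is `NULL`.
#' @param conf_level Confidence level for the d interval.
#' @return A one-row tibble: `mean`, `sd`, `n`, `t`, `df`, `p`, `d`,
#'   `d_se`, `d_ci_low`, `d_ci_high`.
#' @export
#'
#' @examples
#' one_sample_summary(mean = -0.551, sd = 1.920, n = 65)
one_sample_summary <- function(q = NULL, mean = NULL, sd = NULL, n = NULL,
                               conf_level = 0.95) {
  if (!is.null(q)) {
    if (length(q) < 2L) {
      stop_stereolang("stereolang_degenerate_error",
                      "need at least two q scores")
    }
    n <- length(q)
    mean <- base::mean(q)
    sd <- stats::sd(q)
  } else {
    stopifnot(!is.null(mean), !is.null(sd), !is.null(n), n >= 2L)
  }
  if (sd == 0) {
    stop_stereolang("stereolang_degenerate_error",
                    "zero variance in q scores: test undefined")
  }
  tval <- mean / (sd / sqrt(n))
  d <- mean / sd
  d_se <- sqrt(1 / n + d^2 / (2 * n))
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble(mean = mean, sd = sd, n = as.integer(n),
         t = tval, df = as.integer(n - 1L),
         p = 2 * pt(-abs(tval), df = n - 1L),
         d = d, d_se = d_se,
         d_ci_low = d - z * d_se, d_ci_high = d + z * d_se)
}

#' JZS Bayes factor for a one-sample t statistic
#'
#' BF10 for the one-sample design with a Jeffreys-Zellner-Siow setup: a
#' zero-centred Cauchy prior with scale `prior_scale` on the standardized
#' effect, evaluated by numerical integration of the noncentral-t marginal
#' likelihood:
#'
#'   BF10 = \[ integral of t_df(t; delta * sqrt(n)) Cauchy(delta; 0, r)
#'           d delta \] / t_df(t; 0)
#'
#' @param t Observed t statistic.
#' @param n Sample size (df = n - 1).
#' @param prior_scale Cauchy prior scale r (default `sqrt(2) / 2`).
#' @return The Bayes factor BF10 (values < 1 favour the null).
#' @export
jzs_bayes_factor <- function(t, n, prior_scale = sqrt(2) / 2) {
  stopifnot(is.numeric(t), length(t) == 1L, n >= 2L, prior_scale > 0)
  df <- n - 1L
  # the t likelihood is negligible once the noncentrality is ~20 units from
  # t, so the integral is confined to that window (the Cauchy tail outside
  # contributes nothing but would slow the noncentral-t evaluation badly)
  lo <- (t - 20) / sqrt(n)
  hi <- (t + 20) / sqrt(n)
  marginal <- integrate(function(delta) {
    suppressWarnings(dt(t, df = df, ncp = delta * sqrt(n))) *
      dcauchy(delta, location = 0, scale = prior_scale)
  }, lower = lo, upper = hi, rel.tol = 1e-8)
  null_lik <- dt(t, df = df)
  bf <- marginal$value / null_lik
  if (!is.finite(bf)) {
    stop_stereolang("stereolang_numerical_error",
                    "Bayes factor integration did not converge")
  }
  bf
}

#' Correlation between occupational prestige and q scores
#'
#' Pearson correlation over occupations with a valid prestige rating, with
#' the two-sided p-value of `cor.test`.
#'
#' @param probes A scored probe tibble ([score_probes()]) with `prestige`
#'   and `q` columns.
#' @return A one-row tibble: `r`, `p`, `n`.
#' @export
prestige_correlation <- function(probes) {
  stopifnot(all(c("prestige", "q") %in% names(probes)))
  ok <- is.finite(probes$prestige) & is.finite(probes$q)
  x <- probes$prestige[ok]
  y <- probes$q[ok]
  if (length(x) < 3L) {
    stop_stereolang("stereolang_insufficient_data_error",
                    "need at least three occupations with prestige values")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop_stereolang("stereolang_degenerate_error",
                    "zero variance in prestige or q")
  }
  ct <- suppressWarnings(cor.test(x, y))
  tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
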