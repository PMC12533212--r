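#' Specification for a synthetic embedding model with a planted bias
#'
#' The generator plants a controllable association between target words and
#' the high pole of an attribute contrast. Two attribute centroids sit at
#' opposite ends of a random axis; attribute vectors scatter isotropically
#' around their centroid. Each target direction is a convex mixture
#' `bias * axis + (1 - bias) * random direction`, plus Gaussian noise, so
#' `bias = 0` gives null associations and `bias = 1` (low noise) gives
#' uniformly positive association scores.
#'
#' @param dimension Embedding dimension (>= 2).
#' @param n_targets,n_high,n_low Numbers of target and attribute words.
#' @param bias Mixing weight in `[0, 1]` toward the high-attribute centroid.
#' @param noise_sd Isotropic Gaussian noise SD (> 0).
#' @param seed Integer seed.
#' @return An object of class `embedding_spec`.
#' @export
embedding_spec <- function(dimension = 50L, n_targets = 20L, n_high = 25L,
                           n_low = 25L, bias = 0.3, noise_sd = 0.2,
                           seed = 1L) {
  stopifnot(dimension >= 2L, n_targets >= 1L, n_high >= 1L, n_low >= 1L,
            bias >= 0, bias <= 1, noise_sd > 0)
  structure(list(dimension = as.integer(dimension),
                 n_targets = as.integer(n_targets),
                 n_high = as.integer(n_high), n_low = as.integer(n_low),
                 bias = bias, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "embedding_spec")
}

random_unit <- function(n, d) {
  m <- matrix(rnorm(n * d), n, d)
  m / sqrt(rowSums(m^2))
}

#' Generate a synthetic embedding model with known planted bias
#'
#' @param spec An [embedding_spec()].
#' @return A list: `model` (an `embedding_model` whose vocabulary holds the
#'   targets and both attribute sets), `targets` (target [lexicon]), `pair`
#'   (attribute `contrast_pair`), and `truth` (the generating spec object
#'   plus the planted
#'   axis), deterministic per seed.
#' @export
gen_embeddings <- function(spec) {
  stopifnot(inherits(spec, "embedding_spec"))
  set.seed(spec$seed)
  d <- spec$dimension
  axis <- as.vector(random_unit(1L, d))
  high <- random_unit(spec$n_high, d) * spec$noise_sd +
    matrix(axis, spec$n_high, d, byrow = TRUE)
  low <- random_unit(spec$n_low, d) * spec$noise_sd -
    matrix(axis, spec$n_low, d, byrow = TRUE)
  dirs <- random_unit(spec$n_targets, d)
  tgt <- spec$bias * matrix(axis, spec$n_targets, d, byrow = TRUE) +
    (1 - spec$bias) * dirs +
    matrix(rnorm(spec$n_targets * d, sd = spec$noise_sd), spec$n_targets, d)
  words_t <- sprintf("target%03d", seq_len(spec$n_targets))
  words_h <- sprintf("high%03d", seq_len(spec$n_high))
  words_l <- sprintf("low%03d", seq_len(spec$n_low))
  mat <- rbind(tgt, high, low)
  rownames(mat) <- c(words_t, words_h, words_l)
  model <- embedding_model(sprintf("synthetic_seed%d", spec$seed), mat,
                           metadata = "synthetic planted-bias embedding")
  targets <- lexicon("synthetic_targets", words_t, role = "target")
  pair <- make_contrast(
    lexicon("synthetic_high", words_h, role = "attribute",
            polarity = "high", dimension = "planted", source = "synthetic"),
    lexicon("synthetic_low", words_l, role = "attribute",
            polarity = "low", dimension = "planted", source = "synthetic"),
    label = "planted")
  list(model = model, targets = targets, pair = pair,
       truth = list(spec = spec, axis = axis))
}

#' Generate a mock fill-mask fixture with a planted contrast
#'
#' Builds a query set (one template, one target, `n_pairs` attribute pairs)
#' together with a [mock_mask_adapter()] table in which each pair's
#' log-probability contrast equals `delta` plus Gaussian noise. Probability
#' pairs whose high side would exceed 1 are rescaled jointly (a warning is
#' raised), which leaves the contrast untouched.
#'
#' @param delta Planted mean log-probability contrast.
#' @param n_pairs Number of attribute pairs (>= 2).
#' @param noise_sd SD of the per-pair Gaussian deviation from `delta`.
#' @param seed Integer seed.
#' @param base_prob Low-pole probability before any rescaling.
#' @return A list: `adapter`, `queries`, `truth` (delta and per-pair
#'   contrasts), deterministic per seed.
#' @export
gen_fillmask_table <- function(delta, n_pairs = 24L, noise_sd = 0.1,
                               seed = 1L, base_prob = 0.05) {
  stopifnot(n_pairs >= 2L, noise_sd >= 0, base_prob > 0, base_prob <= 1)
  set.seed(seed)
  contrasts <- delta + rnorm(n_pairs, sd = noise_sd)
  pair <- make_contrast(
    lexicon("synthetic_high", sprintf("goodword%03d", seq_len(n_pairs)),
            role = "attribute", polarity = "high", dimension = "planted",
            source = "synthetic"),
    lexicon("synthetic_low", sprintf("badword%03d", seq_len(n_pairs)),
            role = "attribute", polarity = "low", dimension = "planted",
            source = "synthetic"),
    label = "planted")
  targets <- lexicon("synthetic_target", "ai", role = "target")
  queries <- build_queries("The [MASK] is {ATTRIB}.", targets, pair)
  p_low <- rep(base_prob, n_pairs)
  p_high <- base_prob * exp(contrasts)
  over <- p_high > 1
  if (any(over)) {
    warn(sprintf("renormalizing %d probability pair(s) exceeding 1",
                 sum(over)))
    scale <- 1 / p_high[over]
    p_high[over] <- p_high[over] * scale
    p_low[over] <- p_low[over] * scale
  }
  hi <- queries[queries$polarity == "high", ]
  lo <- queries[queries$polarity == "low", ]
  table <- tibble(
    context = c(hi$context, lo$context),
    token = "ai",
    prob = c(p_high[match(hi$attrib_word, pair$high$words)],
             p_low[match(lo$attrib_word, pair$low$words)]))
  list(adapter = mock_mask_adapter(table, model_id = "synthetic_mock"),
       queries = queries,
       truth = list(delta = delta, contrasts = contrasts, seed = seed))
}

#' Specification for a synthetic occupation-probe table
#'
#' Plants a linear relation between standardized occupational prestige and
#' the q score: `q_true = slope * z(prestige) + Gaussian(0, noise_sd)`.
#'
#' @param n_occupations Number of occupations (>= 3).
#' @param prestige_range Lower and upper bounds of the uniform prestige
#'   draw.
#' @param slope Planted effect of standardized prestige on q.
#' @param noise_sd SD of the q noise (>= 0).
#' @param n_obs_per_family Scheduled observations per family (>= 1).
#' @param seed Integer seed.
#' @return An object of class `probe_spec`.
#' @export
probe_spec <- function(n_occupations = 65L, prestige_range = c(20, 80),
                       slope = 0.8, noise_sd = 0.3, n_obs_per_family = 100L,
                       seed = 1L) {
  stopifnot(n_occupations >= 3L, length(prestige_range) == 2L,
            prestige_range[[1L]] < prestige_range[[2L]], noise_sd >= 0,
            n_obs_per_family >= 1L)
  structure(list(n_occupations = as.integer(n_occupations),
                 prestige_range = as.numeric(prestige_range),
                 slope = slope, noise_sd = noise_sd,
                 n_obs_per_family = as.integer(n_obs_per_family),
                 seed = as.integer(seed)),
            class = "probe_spec")
}

#' Generate a synthetic occupation-probe fixture with known q scores
#'
#' The mock provider assigns every occupation a constant replacement-family
#' probability and a benefit-family probability `base * exp(q_true)`, so
#' the sample means over any schedule reproduce `q_true` exactly
#' (`q_score` inverts the construction to machine precision).
#'
#' @param spec A [probe_spec()].
#' @return A list: `occupations` (tibble `occupation`, `prestige`),
#'   `provider` (a [mock_llm_provider()]), `prompts` (a [prompt_set()]
#'   scheduling `n_obs_per_family` appearances per family), `truth`
#'   (`q_true`, the planted slope and the prestige z-scores), deterministic
#'   per seed.
#' @export
gen_probe_table <- function(spec) {
  stopifnot(inherits(spec, "probe_spec"))
  set.seed(spec$seed)
  occ <- sprintf("occupation%03d", seq_len(spec$n_occupations))
  prestige <- runif(spec$n_occupations, spec$prestige_range[[1L]],
                    spec$prestige_range[[2L]])
  z <- as.vector(scale(prestige))
  q_true <- spec$slope * z + rnorm(spec$n_occupations, sd = spec$noise_sd)
  base <- min(0.01, 0.9 / max(exp(q_true)))
  table <- dplyr::bind_rows(
    tibble(family = "replacement", occupation = occ, prob = base),
    tibble(family = "benefit", occupation = occ, prob = base * exp(q_true)))
  provider <- mock_llm_provider(table, top_k = 20L,
                                model_id = "synthetic_mock")
  prompts <- prompt_set(
    benefit_templates =
      "The occupation that is more likely to benefit from Artificial Intelligence is {MASK}.",
    replacement_templates =
      "The job that is most likely to be replaced by Artificial Intelligence is {MASK}.",
    occupations = occ,
    batch_size = min(20L, spec$n_occupations),
    min_appearances = spec$n_obs_per_family,
    seed = spec$seed)
  list(occupations = tibble(occupation = occ, prestige = prestige),
       provider = provider, prompts = prompts,
       truth = list(spec = spec, q_true = setNames(q_true, occ),
                    prestige_z = setNames(z, occ)))
}
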