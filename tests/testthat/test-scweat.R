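test_that("association scores match hand computation and brute force", {
  m <- toy_model(c("w", "hi1", "lo1"), c(1, 0, 1, 0, 0, 1))
  pair <- make_contrast(
    lexicon("h", "hi1", "attribute", "high", "dim"),
    lexicon("l", "lo1", "attribute", "low", "dim"))
  rec <- association_score(m, "w", pair)
  expect_equal(rec$score, 1)
  expect_equal(rec$n_high, 1L)
  expect_equal(rec$n_low, 1L)

  # equidistant target scores zero
  m2 <- toy_model(c("w", "hi1", "lo1"), c(1, 1, 1, 0, 0, 1))
  expect_equal(association_score(m2, "w", pair)$score, 0, tolerance = 1e-12)

  # brute-force oracle agreement on a 5-word toy set
  fx <- perm_fixture()
  for (tw in fx$targets$words) {
    expect_equal(association_score(fx$model, tw, fx$pair)$score,
                 brute_association(fx$model, tw, fx$pair$high$words,
                                   fx$pair$low$words),
                 tolerance = 1e-12)
  }
})

test_that("association scores are antisymmetric under contrast mirroring", {
  fx <- perm_fixture()
  for (tw in fx$targets$words) {
    expect_equal(association_score(fx$model, tw, fx$pair)$score,
                 -association_score(fx$model, tw, mirror_contrast(fx$pair))$score,
                 tolerance = 1e-12)
  }
})

test_that("OOV handling distinguishes error and skip policies", {
  m <- toy_model(c("w", "hi1", "lo1"), c(1, 0, 1, 0, 0, 1))
  pair <- make_contrast(
    lexicon("h", c("hi1", "ghost"), "attribute", "high", "dim"),
    lexicon("l", "lo1", "attribute", "low", "dim"))
  expect_error(association_score(m, "w", pair), class = "stereolang_oov_error")
  expect_warning(rec <- association_score(m, "w", pair, oov = "skip"), "ghost")
  expect_equal(rec$n_high, 1L)

  targets <- lexicon("tg", c("w", "missing"), "target")
  pair_ok <- make_contrast(
    lexicon("h", "hi1", "attribute", "high", "dim"),
    lexicon("l", "lo1", "attribute", "low", "dim"))
  expect_warning(
    recs <- association_scores(m, targets, pair_ok, oov_targets = "skip"),
    "missing")
  expect_equal(nrow(recs), 1L)
})

test_that("scweat_effect is the standardized mean with degenerate guards", {
  recs <- tibble::tibble(score = c(0.1, 0.3), contrast = "dim")
  eff <- scweat_effect(recs)
  expect_equal(eff$estimate, 0.2 / sqrt(0.02), tolerance = 1e-5)
  expect_equal(eff$estimate, 1.41421, tolerance = 1e-5)
  expect_equal(eff$se, 1 / sqrt(2))

  sym <- tibble::tibble(score = c(0.4, -0.4), contrast = "dim")
  expect_equal(scweat_effect(sym)$estimate, 0)

  flat <- tibble::tibble(score = c(0.2, 0.2, 0.2), contrast = "dim")
  expect_error(scweat_effect(flat), class = "stereolang_degenerate_error")
})

test_that("exhaustive permutation p-values equal the brute-force enumeration", {
  fx <- perm_fixture()
  p_exh <- permutation_pvalue(fx$model, fx$targets, fx$pair,
                              n_perm = "exhaustive")
  p_brute <- brute_permutation_p(fx$model, fx$targets$words,
                                 fx$pair$high$words, fx$pair$low$words)
  expect_equal(p_exh, p_brute, tolerance = 1e-12)
  # planted maximal separation: only the observed partition attains the max
  expect_equal(p_exh, 1 / choose(4, 2), tolerance = 1e-12)
})

test_that("sampled permutation p-values use add-one smoothing and a seed", {
  fx <- perm_fixture()
  p1 <- permutation_pvalue(fx$model, fx$targets, fx$pair, n_perm = 199,
                           seed = 42)
  p2 <- permutation_pvalue(fx$model, fx$targets, fx$pair, n_perm = 199,
                           seed = 42)
  expect_identical(p1, p2)
  expect_gte(p1, 1 / 200)
  expect_lte(p1, 1)
  # smoothing: p is a multiple of 1/(n_perm + 1)
  expect_equal((p1 * 200) %% 1, 0, tolerance = 1e-9)
  expect_error(
    permutation_pvalue(fx$model, fx$targets, fx$pair, n_perm = 10),
    class = "stereolang_schema_error")
})

test_that("permutation p-values are approximately uniform under the null", {
  # small null embeddings; repeat over seeds and check the empirical
  # type-I rate at alpha = 0.25 (wider alpha keeps Monte-Carlo error small)
  ps <- sapply(1:40, function(s) {
    g <- gen_embeddings(embedding_spec(dimension = 8, n_targets = 4,
                                       n_high = 4, n_low = 4, bias = 0,
                                       noise_sd = 1, seed = 1000 + s))
    permutation_pvalue(g$model, g$targets, g$pair, n_perm = "exhaustive")
  })
  rate <- mean(ps <= 0.25)
  expect_gt(rate, 0.05)
  expect_lt(rate, 0.5)
})

test_that("pooled regression recovers closed-form group means and the null", {
  # two models, polarity means +/- 0.25 after standardization by
  # construction: slope must be 0.5
  sims <- tibble::tibble(
    target = "t", attribute = rep(c("a", "b"), each = 4),
    polarity = rep(c(1L, 0L), each = 4),
    similarity = c(0.25 + c(-1, 1, -2, 2) * 0.570087712549569,
                   -0.25 + c(-1, 1, -2, 2) * 0.570087712549569),
    contrast = "dim", model_id = "m1", dictionary_id = "d1")
  # verify the fixture is standardized as intended, then the slope
  expect_equal(sd(sims$similarity), 1, tolerance = 1e-9)
  eff <- pooled_regression(sims)
  expect_equal(eff$estimate, 0.5, tolerance = 1e-9)

  # identical distributions in both polarities: estimate ~ 0
  null_sims <- tibble::tibble(
    target = "t", attribute = letters[1:8],
    polarity = rep(c(1L, 0L), each = 4),
    similarity = rep(c(0.1, 0.2, 0.3, 0.4), times = 2),
    contrast = "dim", model_id = "m1", dictionary_id = "d1")
  expect_equal(pooled_regression(null_sims)$estimate, 0, tolerance = 1e-12)

  expect_error(pooled_regression(dplyr::filter(null_sims, polarity == 1L)),
               class = "stereolang_design_error")
})

test_that("pooled regression is antisymmetric and order-invariant", {
  g <- gen_embeddings(embedding_spec(n_targets = 12, bias = 0.4, seed = 5))
  sims <- similarity_long(g$model, g$targets, g$pair)
  sims_m <- similarity_long(g$model, g$targets, mirror_contrast(g$pair))
  e1 <- pooled_regression(sims)$estimate
  expect_equal(e1, -pooled_regression(sims_m)$estimate, tolerance = 1e-9)

  shuffled <- sims[rev(seq_len(nrow(sims))), ]
  expect_equal(pooled_regression(shuffled)$estimate, e1, tolerance = 1e-9)

  # scweat_effect agrees in sign with the pooled slope on planted bias
  eff <- scweat_effect(association_scores(g$model, g$targets, g$pair))
  expect_equal(sign(eff$estimate), sign(e1))
})

test_that("standardization is applied within each model-dictionary cell", {
  g1 <- gen_embeddings(embedding_spec(n_targets = 10, bias = 0.4, seed = 21))
  s1 <- similarity_long(g1$model, g1$targets, g1$pair)
  # a second 'model': same geometry, similarities rescaled (different scale)
  s2 <- dplyr::mutate(s1, similarity = similarity * 7, model_id = "rescaled")
  pooled <- pooled_regression(dplyr::bind_rows(s1, s2))
  solo <- pooled_regression(s1)
  # scale differences are absorbed: pooling a rescaled copy changes nothing
  expect_equal(pooled$estimate, solo$estimate, tolerance = 1e-9)
})
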