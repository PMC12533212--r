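test_that("make_batches schedules enough appearances deterministically", {
  ps <- prompt_set("benefit {MASK}", "replace {MASK}",
                   sprintf("occ%02d", 1:20), batch_size = 20,
                   min_appearances = 3, seed = 5)
  tasks <- make_batches(ps)
  # degenerate batching: every batch is the full list
  expect_true(all(lengths(tasks$candidates) == 20L))
  for (fam in c("benefit", "replacement")) {
    counts <- table(unlist(tasks$candidates[tasks$family == fam]))
    expect_true(all(counts >= 3L))
  }

  ps2 <- prompt_set("benefit {MASK}", "replace {MASK}",
                    sprintf("occ%02d", 1:40), batch_size = 20,
                    min_appearances = 10, seed = 5)
  tasks2 <- make_batches(ps2)
  for (fam in c("benefit", "replacement")) {
    counts <- table(unlist(tasks2$candidates[tasks2$family == fam]))
    expect_equal(length(counts), 40L)
    expect_true(all(counts >= 10L))
  }

  expect_identical(make_batches(ps2), make_batches(ps2))
  expect_error(make_batches(ps2, max_iter = 2L),
               class = "stereolang_iteration_cap_error")
  expect_error(prompt_set("b", "r", c("a", "b"), batch_size = 3),
               class = "stereolang_content_error")
})

test_that("collect_probabilities reproduces a fixed mock table verbatim", {
  table <- tibble::tibble(
    family = rep(c("benefit", "replacement"), each = 3),
    occupation = rep(c("doctor", "cleaner", "teacher"), 2),
    prob = c(0.4, 0.1, 0.2, 0.1, 0.3, 0.2))
  provider <- mock_llm_provider(table, top_k = 20)
  tasks <- tibble::tibble(
    task_id = c("b1", "r1"), family = c("benefit", "replacement"),
    template = "t", candidates = list(c("doctor", "cleaner", "teacher"),
                                      c("doctor", "cleaner", "teacher")))
  probes <- collect_probabilities(provider, tasks)
  expect_equal(probes$n1, rep(1L, 3))
  expect_equal(probes$p_benefit[[which(probes$occupation == "doctor")]], 0.4)
  expect_equal(probes$p_replacement[[which(probes$occupation == "cleaner")]],
               0.3)

  # same provider and schedule: identical output
  expect_identical(collect_probabilities(provider, tasks),
                   collect_probabilities(provider, tasks))
})

test_that("occupations outside the top-k contribute no observation", {
  table <- tibble::tibble(
    family = "benefit",
    occupation = c("a", "b", "c"),
    prob = c(0.5, 0.3, 0.1))
  provider <- mock_llm_provider(table, top_k = 2)
  tasks <- tibble::tibble(task_id = "b1", family = "benefit", template = "t",
                          candidates = list(c("a", "b", "c")))
  expect_warning(probes <- collect_probabilities(provider, tasks), "c")
  expect_false("c" %in% probes$occupation)
  expect_equal(probes$n1[probes$occupation == "b"], 1L)
})

test_that("q_score matches the hand-evaluated log mean ratio", {
  expect_equal(q_score(c(0.02, 0.04), c(0.01, 0.02)), log(2))
  expect_equal(q_score(c(0.02, 0.04), c(0.01, 0.02)), 0.69315,
               tolerance = 1e-5)
  expect_equal(q_score(c(0.3, 0.1), c(0.1, 0.3)), 0)
  expect_error(q_score(numeric(0), 0.1),
               class = "stereolang_insufficient_data_error")
})

test_that("q is antisymmetric under family swap and scale-invariant", {
  set.seed(12)
  for (i in 1:10) {
    pb <- runif(5, 0.01, 0.5)
    pr <- runif(7, 0.01, 0.5)
    q <- q_score(pb, pr)
    expect_equal(q_score(pr, pb), -q, tolerance = 1e-12)
    expect_equal(q_score(pb * 0.3, pr * 0.3), q, tolerance = 1e-12)
  }
})

test_that("one_sample_summary matches the closed form on fixtures", {
  set.seed(4)
  q <- rnorm(30, mean = -0.3, sd = 1.2)
  s <- one_sample_summary(q)
  expect_equal(s$t, mean(q) / (sd(q) / sqrt(30)), tolerance = 1e-12)
  expect_equal(s$d * s$sd, s$mean, tolerance = 1e-12)
  expect_equal(s$p, t.test(q)$p.value, tolerance = 1e-12)
  expect_equal(s$df, 29L)

  expect_error(one_sample_summary(rep(0, 5)),
               class = "stereolang_degenerate_error")
})

test_that("JZS Bayes factor favours the null at t = 0 and grows with |t|", {
  expect_lt(jzs_bayes_factor(0, 65), 1)
  grid <- seq(0, 4, by = 0.5)
  bfs <- sapply(grid, jzs_bayes_factor, n = 40)
  expect_true(all(diff(bfs) > 0))
  expect_equal(jzs_bayes_factor(-2, 40), jzs_bayes_factor(2, 40),
               tolerance = 1e-6)

  # independent oracle: trapezoidal integration on a fine delta grid over
  # the region where the noncentral-t likelihood is non-negligible
  oracle_bf <- function(t, n, r = sqrt(2) / 2) {
    delta <- seq((t - 25) / sqrt(n), (t + 25) / sqrt(n),
                 length.out = 20001)
    f <- suppressWarnings(dt(t, df = n - 1, ncp = delta * sqrt(n))) *
      dcauchy(delta, 0, r)
    num <- sum((f[-1] + f[-length(f)]) / 2) * diff(delta)[1]
    num / dt(t, df = n - 1)
  }
  for (tv in c(-2.311, 0.8, 3)) {
    expect_equal(jzs_bayes_factor(tv, 65), oracle_bf(tv, 65),
                 tolerance = 1e-3)
  }
})

test_that("prestige correlation matches hand-computed values", {
  probes1 <- tibble::tibble(prestige = c(1, 2, 3), q = c(1, 3, 5))
  expect_equal(prestige_correlation(probes1)$r, 1, tolerance = 1e-12)

  probes2 <- tibble::tibble(prestige = c(1, 2, 3), q = c(1, 2, 2))
  expect_equal(prestige_correlation(probes2)$r, sqrt(3) / 2,
               tolerance = 1e-9)
  expect_equal(prestige_correlation(probes2)$r, 0.866, tolerance = 1e-3)

  probes3 <- tibble::tibble(prestige = c(1, 2, 3), q = -c(1, 2, 3))
  expect_equal(prestige_correlation(probes3)$r, -1, tolerance = 1e-12)

  # missing prestige rows are excluded from n
  probes4 <- tibble::tibble(prestige = c(1, 2, 3, NA), q = c(1, 3, 5, 9))
  expect_equal(prestige_correlation(probes4)$n, 3L)

  expect_error(prestige_correlation(tibble::tibble(prestige = c(1, 1, 1),
                                                   q = c(1, 2, 3))),
               class = "stereolang_degenerate_error")
})

test_that("planted prestige-q relationships are recovered across seeds", {
  rs <- sapply(1:5, function(s) {
    pt <- gen_probe_table(probe_spec(n_occupations = 40, slope = 0.8,
                                     noise_sd = 0.3, n_obs_per_family = 5,
                                     seed = s))
    tasks <- make_batches(pt$prompts)
    probes <- collect_probabilities(
      pt$provider, tasks,
      prestige = setNames(pt$occupations$prestige,
                          pt$occupations$occupation))
    prestige_correlation(score_probes(probes))$r
  })
  implied <- 0.8 / sqrt(0.8^2 + 0.3^2)
  expect_equal(mean(rs), implied, tolerance = 0.1)
})
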