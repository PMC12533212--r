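# Small deterministic fixtures shared across test files.

toy_model <- function(words, vectors) {
  mat <- matrix(vectors, nrow = length(words), byrow = TRUE,
                dimnames = list(words, NULL))
  embedding_model("toy", mat)
}

# 2D model with two targets and 2+2 attribute words, separated enough that
# permutation statistics are distinct across partitions.
perm_fixture <- function() {
  m <- toy_model(c("t1", "t2", "a1", "a2", "b1", "b2"),
                 c(1, 0.2,
                   0.9, 0.1,
                   1, 0,
                   0.8, 0.2,
                   0.1, 0.9,
                   0, 1))
  list(model = m,
       targets = lexicon("tg", c("t1", "t2"), "target"),
       pair = make_contrast(
         lexicon("hi", c("a1", "a2"), "attribute", "high", "dim"),
         lexicon("lo", c("b1", "b2"), "attribute", "low", "dim")))
}

competence_pair <- function(high = "smart", low = "dumb") {
  make_contrast(
    lexicon("hi", high, "attribute", "high", "competence", "toy_dict"),
    lexicon("lo", low, "attribute", "low", "competence", "toy_dict"))
}

# Brute-force SC-WEAT association score: plain loops, no shared code path.
brute_association <- function(model, target, high_words, low_words) {
  cos_raw <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  w <- model$vectors[target, ]
  hi <- sapply(high_words, function(a) cos_raw(w, model$vectors[a, ]))
  lo <- sapply(low_words, function(a) cos_raw(w, model$vectors[a, ]))
  mean(hi) - mean(lo)
}

# Brute-force exhaustive permutation p-value over all re-partitions of the
# pooled attribute set into sets of the original sizes.
brute_permutation_p <- function(model, target_words, high_words, low_words) {
  pooled <- c(high_words, low_words)
  stat <- function(hi_idx) {
    hw <- pooled[hi_idx]
    lw <- pooled[-hi_idx]
    mean(sapply(target_words, brute_association, model = model,
                high_words = hw, low_words = lw))
  }
  observed <- stat(seq_along(high_words))
  combos <- utils::combn(length(pooled), length(high_words), simplify = FALSE)
  mean(sapply(combos, stat) >= observed)
}
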