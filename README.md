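# stereolang

Language-based measurement of social stereotypes about artificial
intelligence.

Natural language is a repository of shared social beliefs: how a linguistic
community talks about AI encodes whether AI is seen as competent or warm,
which social groups it is associated with, and which occupations are
expected to benefit from it rather than be replaced by it. stereolang
implements a tiered pipeline for quantifying those associations, aimed at
computational social scientists who want each tier to be testable offline,
with synthetic inputs of known ground truth, before any corpus, model
download or API key is involved.

The four tiers:

* **SC-WEAT** — the Single-Category Word Embedding Association Test. For a
  target word *w* and contrasting attribute sets *A*, *B*:
  `s(w) = mean_a cos(w, a) − mean_b cos(w, b)`, summarized either as the
  classic effect `d = mean(s)/sd(s)` or by a pooled regression of
  unit-SD-standardized (target × attribute) similarities on the attribute
  polarity, whose slope is directly a Cohen's-d-equivalent effect.
  Permutation inference (exhaustive or seeded Monte-Carlo with add-one
  smoothing) re-partitions the attribute sets.
* **FMAT** — the Fill-Mask Association Test. Propositional queries
  ("The [MASK] is {ATTRIB}.") are scored by any adapter exposing
  `p(token at mask | context)`; per-pair contrasts
  `log p_high − log p_low` are standardized within model and pooled.
* **Stereotype space** — each group becomes a 4D point (competence and
  warmth under two attribute dictionaries); Euclidean distances from AI to
  each group are contrasted between advantaged and disadvantaged groups
  with a method fixed effect.
* **Occupation probe** — batched benefit / replacement prompts against a
  top-k generative-LM readout yield per-occupation scores
  `q = ln(mean p_benefit / mean p_replacement)`, with one-sample t,
  Cohen's d and its CI, a JZS Bayes factor, and the correlation of q with
  occupational prestige.

Effects from the embedding and masked-LM tiers share the Cohen's-d scale
and can be pooled by the built-in fixed / DerSimonian–Laird / REML
meta-analysis.

## Worked example

Plant a known association bias in a synthetic embedding and recover it:

```r
library(stereolang)

g <- gen_embeddings(embedding_spec(dimension = 50, n_targets = 50,
                                   bias = 0.3, noise_sd = 0.2, seed = 42))
sims <- similarity_long(g$model, g$targets, g$pair)
pooled_regression(sims)
#> # A tibble: 1 × 9
#>   estimate     se ci_low ci_high     p n_obs method        study dimension
#>      <dbl>  <dbl>  <dbl>   <dbl> <dbl> <int> <chr>         <chr> <chr>
#> 1     1.53 0.0257   1.48    1.58     0  2500 scweat_pooled <NA>  planted
```

The slope 1.53 says the planted targets sit 1.5 standardized units closer
to the high-attribute pole — strongly positive, as constructed (bias 0.3
over noise 0.2); at `bias = 0` the same estimate is near zero.

Reproduce a published one-sample occupation-probe summary from its printed
moments (mean q −0.551, SD 1.920, 65 occupations):

```r
one_sample_summary(mean = -0.551, sd = 1.920, n = 65)
#>     mean   sd  n      t df     p      d  d_se d_ci_low d_ci_high
#> 1 -0.551 1.92 65 -2.314 64 0.024 -0.287 0.127   -0.535    -0.039
jzs_bayes_factor(-2.314, n = 65)
#> [1] 1.613
```

The mean q is reliably negative by the t-test (occupations lean toward
"replaced by AI"), but the Bayes factor of 1.6 marks that evidence as weak.

Pool four standardized competence coefficients (two embedding dictionaries,
two masked-LM dictionaries) with REML:

```r
pool_effects(c(0.612, 0.293, 0.311, 0.097),
             c(0.041, 0.005, 0.007, 0.005)^2, model = "reml_random")
#>   pooled    se ci_low ci_high     p  tau2 k
#> 1  0.326 0.105  0.120   0.531 0.002 0.044 4
```

A medium pooled competence effect (d = 0.326) with substantial
between-method heterogeneity (tau² = 0.044).

Real data enter through the same surfaces: `read_embeddings()` (GloVe /
word2vec text formats), `read_lexicon()` (CSV/JSON word lists; small
illustrative ones ship in `inst/extdata/`), `mock_mask_adapter()` /
`mock_llm_provider()` replaced by live backends satisfying the same
contracts.

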