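---
title: "Measuring language-based stereotypes about AI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring language-based stereotypes about AI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereolang)
```

## What the package measures

Social perception organizes groups along two stereotype dimensions —
*warmth* (is this target a friend or a foe?) and *competence* (can it act
on its intentions?). stereolang quantifies where the concept of artificial
intelligence sits along these dimensions, and relative to social groups, in
three tiers of natural-language representation:

1. **SC-WEAT** (Single-Category Word Embedding Association Test) on static
   word embeddings: word-level associations via cosine similarity.
2. **FMAT** (Fill-Mask Association Test) on masked language models:
   sentence-level associations via fill-mask probabilities.
3. A **log-probability-ratio probe** of generative models: discourse-level
   associations between occupations and AI's perceived benefit versus
   threat.

Effects from the first two tiers are placed on a common Cohen's-d scale and
pooled with an internal random-effects meta-analysis; the third tier
produces per-occupation q scores with one-sample inference and a prestige
correlation. Every stage can be driven entirely by the seeded
synthetic-data generators, so the full pipeline is testable offline with
known ground truth.

## SC-WEAT

For a target word $w$ and attribute sets $A$ (high pole) and $B$ (low
pole), the association score is

$$s(w) = \frac{1}{|A|}\sum_{a \in A}\cos(w, a) -
          \frac{1}{|B|}\sum_{b \in B}\cos(w, b),$$

bounded in $[-2, 2]$. Two summaries are provided:

* `scweat_effect()`: the classic single-category effect size
  $d = \bar{s}/\mathrm{sd}(s)$ over target words, with SE $1/\sqrt{n}$ and
  a one-sample t p-value.
* `pooled_regression()`: the observation unit is the individual
  (target word × attribute word) cosine similarity. Similarities are scaled
  to unit standard deviation *within each embedding-model ×
  attribute-dictionary cell* — embeddings differ substantially in their raw
  similarity scales — and the standardized similarity is regressed on the
  attribute-polarity indicator (high = 1, low = 0). The OLS slope is then a
  standardized mean difference, i.e. a Cohen's-d-equivalent effect, and
  several models and dictionaries can be pooled in one fit.

The observation unit for the pooled regression was a genuinely open design
choice; we regress per target×attribute similarities rather than per-target
difference scores because it keeps both polarities as data rows (the
polarity indicator then has a defined slope) and matches the large
degrees-of-freedom scale of regression-based effect reporting. Per-model
effects remain available through `scweat_effect()`.

Inference beyond the regression p-value is available from
`permutation_pvalue()`, which re-partitions the pooled attribute words into
high/low sets of the original sizes. Exhaustive mode enumerates all
partitions and reports the exact fraction whose mean association reaches
the observed one; Monte-Carlo mode samples partitions and applies add-one
smoothing $(k+1)/(n+1)$ so the p-value is never zero. The seed is a
required argument in Monte-Carlo mode: silent irreproducibility is worse
than a mandatory parameter.

**Out-of-vocabulary policy.** Lexeme resolution fails hard by default; a
`oov = "skip"` option drops unresolvable attribute words (and
`oov_targets = "skip"` drops target words) with a warning and records the
reduced attribute counts. Silent dropping changes effect sizes invisibly,
so skipping is never the default. Multiword lexemes ("artificial
intelligence") resolve to the unweighted mean of their token vectors — the
standard static-embedding practice — and this choice is deliberately
documented rather than hidden because phrase vectorization is not uniquely
defined.

## FMAT

`build_queries()` renders propositional templates ("The [MASK] is
{ATTRIB}.") against a target lexicon and positionally matched attribute
pairs; the target word's probability at the mask is read from an injectable
adapter. The shipped adapter is a deterministic `(context, token) →
probability` lookup table (`mock_mask_adapter()`), which makes the whole
module byte-reproducible; a live masked-LM backend satisfying the same
contract can be swapped in without touching any analysis code. Targets the
adapter cannot tokenize are skipped and logged, dropping both variants of
the affected pair.

Per pair, the contrast is $\log p_{\text{high}} - \log p_{\text{low}}$
(natural logarithms throughout, for consistency with the q score below).
`fmat_association()` scales contrasts to unit SD within each model and
reports the mean standardized contrast with its OLS standard error — the
same Cohen's-d-equivalent scale as the pooled SC-WEAT slope.

## The 4D competence–warmth space

Each group's position is the 4-vector of its association effects:
competence and warmth measured with each of two attribute dictionaries,
assembled in a fixed canonical order by `build_point()`. Distances between
AI and each group are Euclidean (`euclidean_distance()`), computed only
within a method (SC-WEAT points and FMAT points are never compared
directly). `advantaged_contrast()` regresses distance on a
disadvantaged-status indicator with a method fixed effect, so any additive
method-level offset in distances is absorbed; a positive slope means the
disadvantaged groups sit farther from AI. Coordinates are used on each
dictionary's native effect scale, unstandardized within the 4-vector; with
only a handful of group×method records, unweighted OLS is the parsimonious
model and no covariance weighting is attempted.

## The occupation probe and the q score

Two prompt families ask a generative model which occupation is most likely
to *benefit from* AI and which is most likely to be *replaced by* it. Each
task embeds a random batch of candidate occupations (default batch size 20)
and the provider returns its top-k completions with probabilities (default
k = 20, mirroring the readout of commercial APIs). Batches are drawn until
every occupation is scheduled at least `min_appearances` times per family
(default 100). Candidates absent from a task's top-k contribute *no*
observation — not a zero and not an epsilon floor. Imputing a probability
floor would fabricate information; the repetition requirement exists
precisely so that missingness is absorbed by sampling.

Per occupation $x$,

$$q(x) = \ln\frac{\tfrac{1}{n_1}\sum_i p(x \mid v_{\text{benefit}}(t_i))}
                 {\tfrac{1}{n_2}\sum_j p(x \mid v_{\text{replacement}}(t_j))},$$

so $q > 0$ means the occupation is associated more with benefiting from AI
than with being replaced by it. q is exactly antisymmetric under exchanging
the families and invariant under a global rescaling of probabilities.

`one_sample_summary()` tests the mean q against zero ($t = \bar q /
(s/\sqrt n)$, $d = \bar q / s$) and reports a normal-approximation 95% CI
for d with $\mathrm{SE}(d) = \sqrt{1/n + d^2/(2n)}$ — the standard
one-sample approximation, which also reproduces published intervals of
this design to the third decimal. It accepts either raw scores or printed
summary moments, so published results can be checked without the raw
probability logs.

`jzs_bayes_factor()` computes the one-sample Jeffreys–Zellner–Siow Bayes
factor by numerically integrating the noncentral-t marginal likelihood
against a zero-centred Cauchy prior on the standardized effect. The default
prior scale is $\sqrt{2}/2$, the convention of common Bayes-factor
software, and is exposed as a parameter. Numerically, the integration is
confined to the noncentrality window $t \pm 20$: outside it the t
likelihood is vanishingly small while the noncentral-t density becomes
slow and unstable to evaluate, so truncation both stabilizes and
accelerates the quadrature at no accuracy cost (the suite checks it
against an independent trapezoidal oracle).

`prestige_correlation()` is a plain Pearson correlation between
occupational prestige and q over occupations with a valid prestige rating.

## Internal meta-analysis

`pool_effects()` pools Cohen's-d-scale effects with known variances under a
common-effect model, DerSimonian–Laird moments, or REML (the default, the
convention of standard meta-analytic software). The REML criterion is
maximized by one-dimensional optimization with an explicit admissibility
check at the $\tau^2 = 0$ boundary. Effect variances for SC-WEAT/FMAT
inputs are the squared standard errors of the corresponding regression
estimates — the only uncertainty the upstream pipeline produces. The
machinery is implemented in the package; the test suite cross-checks it
against the independent `metafor` implementation.

## Synthetic-data generators

The generators produce inputs with exactly the statistical structure the
analyses assume, plus a ground-truth record sufficient for
parameter-recovery tests.

* `gen_embeddings()`: attribute vectors scatter isotropically (Gaussian,
  `noise_sd`) around two centroids at opposite ends of a random axis;
  target directions are the mixture `bias·axis + (1-bias)·random
  direction` plus Gaussian noise. `bias = 0` is an exact null; `bias = 1`
  with small noise makes every association score positive by construction.
  Defaults (dimension 50, 25 attribute words per pole, noise 0.2) give the
  moderate signal-to-noise regime in which realistic standardized effects
  (d roughly 0.15–0.4) are recoverable but not trivial.
* `gen_fillmask_table()`: plants per-pair log-probability contrasts
  `delta + N(0, noise_sd)` into a mock-adapter table; probability pairs
  that would exceed 1 are rescaled jointly (warning), which preserves the
  contrast exactly.
* `gen_probe_table()`: plants `q_true = slope · z(prestige) + N(0,
  noise_sd)` by giving each occupation a constant replacement probability
  and a benefit probability `base · exp(q_true)`. Because the per-family
  probabilities are constant, sample means over any schedule equal the
  planted values and `q_score()` inverts the construction to machine
  precision — a deliberate design that separates the scheduling/collection
  logic from distributional noise.

All generators are pure functions of their spec (seed included) and Gaussian
noise is used throughout, as the analyses make no stronger distributional
assumptions.

**What the generators do not emulate.** Real embeddings have anisotropic,
heavy-tailed similarity structure, polysemy and frequency artefacts; real
masked-LM probabilities correlate across templates; real top-k readouts
have position and phrasing effects. Passing recovery tests therefore shows
the estimators are correct *given the assumed structure*, not that the
published coefficients from five downloadable embeddings, thirty BERT-family
models, or a commercial generative API are reproducible on this machine —
those require the external resources and are explicitly out of scope for the
test suite.

## Problem sizes and numerical choices

The test suite and the acceptance script run at deliberately small sizes
chosen as the package's own verification conditions: null-bias calibration
at 200 target words averaged over 20 seeded replicates (the per-seed
sampling error of the standardized slope at this size is roughly 0.1, so a
single replicate is not a meaningful null check); planted fill-mask
contrast at 100 pairs; probe recovery with 65 occupations and 100
scheduled appearances per family. Exhaustive permutation enumeration is
used whenever the attribute sets are small enough; degenerate inputs (zero
vectors, zero variance, single polarity, empty families) raise classed
errors rather than returning NaN, and ties in the permutation statistic
are counted conservatively (a partition matching the observed statistic
counts toward the p-value).

## Known limitations

* Static-embedding OOV handling is lookup-only; subword reconstruction for
  FastText-style models is not implemented.
* FMAT multiword targets must be single adapter-vocabulary tokens; the
  multi-mask fallback is deliberately not enabled by default because its
  probability semantics are not comparable across models.
* The 4D-space contrast treats the 8 group×method distance records as
  independent observations; with so few records the p-value is indicative
  rather than rigorous, matching the descriptive role of that analysis.
* The JZS Bayes factor assumes the one-sample design; paired or two-sample
  variants are out of scope.
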