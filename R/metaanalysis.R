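#' Internal meta-analysis of standardized effects
#'
#' Pools a set of effect estimates (Cohen's-d scale) with known sampling
#' variances, under a common-effect (fixed) model or a random-effects model
#' with between-source variance tau^2 estimated by DerSimonian-Laird moments
#' or by REML. The pooling machinery is authored here; the `metafor` package
#' is used only as an independent cross-check in the test suite.
#'
#' Fixed: weights `w_i = 1 / v_i`, pooled = weighted mean, `tau2 = 0`.
#' DerSimonian-Laird: `tau2 = max(0, (Q - (k - 1)) / C)` with
#' `Q = sum w_i (d_i - dbar)^2` and `C = sum w_i - sum w_i^2 / sum w_i`,
#' then re-weighting with `w_i* = 1 / (v_i + tau2)`.
#' REML: `tau2` maximizes the restricted log-likelihood, found by
#' one-dimensional optimization.
#'
#' @param effects Numeric vector of effect estimates.
#' @param variances Numeric vector of their sampling variances (positive).
#' @param model `"reml_random"` (default), `"dl_random"` or `"fixed"`.
#' @param labels Optional source labels.
#' @param conf_level Confidence level of the pooled interval.
#'
#' @return A one-row tibble: `pooled`, `se`, `ci_low`, `ci_high`, `p`,
#'   `tau2`, `q_het` (Cochran's Q), `k`, `model`.
#' @export
#'
#' @examples
#' pool_effects(c(0.2, 0.4), c(0.01, 0.01), model = "dl_random")
pool_effects <- function(effects, variances,
                         model = c("reml_random", "dl_random", "fixed"),
                         labels = NULL, conf_level = 0.95) {
  model <- match.arg(model)
  stopifnot(is.numeric(effects), is.numeric(variances),
            length(effects) == length(variances))
  if (any(variances <= 0)) {
    stop_stereolang("stereolang_content_error", "variances must be positive")
  }
  k <- length(effects)
  if (k < 1L) {
    stop_stereolang("stereolang_insufficient_data_error", "no effects supplied")
  }
  if (k < 2L && model != "fixed") {
    stop_stereolang("stereolang_insufficient_data_error",
                    "random-effects pooling needs at least two effects")
  }
  w_fixed <- 1 / variances
  pooled_fixed <- sum(w_fixed * effects) / sum(w_fixed)
  q_het <- sum(w_fixed * (effects - pooled_fixed)^2)
  tau2 <- switch(model,
    fixed = 0,
    dl_random = {
      c_const <- sum(w_fixed) - sum(w_fixed^2) / sum(w_fixed)
      max(0, (q_het - (k - 1)) / c_const)
    },
    reml_random = reml_tau2(effects, variances))
  w <- 1 / (variances + tau2)
  pooled <- sum(w * effects) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble(pooled = pooled, se = se,
         ci_low = pooled - z * se, ci_high = pooled + z * se,
         p = 2 * pnorm(-abs(pooled / se)),
         tau2 = tau2, q_het = q_het, k = as.integer(k), model = model)
}

# Restricted maximum-likelihood tau^2 for the random-effects model:
# maximizes -1/2 [ sum log(v_i + t) + log sum 1/(v_i + t)
#                  + sum (d_i - dbar(t))^2 / (v_i + t) ] over t >= 0.
reml_tau2 <- function(effects, variances) {
  nll <- function(tau2) {
    w <- 1 / (variances + tau2)
    mu <- sum(w * effects) / sum(w)
    0.5 * (sum(log(variances + tau2)) + log(sum(w)) +
             sum(w * (effects - mu)^2))
  }
  upper <- max(1e-8, 10 * (sd(effects)^2 + max(variances)))
  opt <- optimize(nll, interval = c(0, upper))
  # the boundary tau2 = 0 is admissible; prefer it when it fits as well
  if (nll(0) <= opt$objective + 1e-10) 0 else opt$minimum
}
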