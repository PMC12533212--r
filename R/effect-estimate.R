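#' Construct an effect estimate record
#'
#' A single standardized effect estimate with its uncertainty, used as the
#' common return type of [scweat_effect()], [pooled_regression()],
#' [fmat_association()] and [advantaged_contrast()]. Estimates on this scale
#' are interpretable as Cohen's *d*: observations are standardized to unit
#' standard deviation before the contrast is computed, so a slope of 0.3
#' means the two poles differ by 0.3 standard deviations.
#'
#' @param estimate Standardized effect (Cohen's-d-equivalent slope or mean).
#' @param se Standard error of the estimate (non-negative).
#' @param p Two-sided p-value.
#' @param n_obs Number of observations the estimate is based on.
#' @param method,study,dimension Free-text source labels.
#' @param conf_level Confidence level for the symmetric normal interval.
#'
#' @return A one-row tibble with columns `estimate`, `se`, `ci_low`,
#'   `ci_high`, `p`, `n_obs`, `method`, `study`, `dimension`.
#' @export
effect_estimate <- function(estimate, se, p, n_obs,
                            method = NA_character_, study = NA_character_,
                            dimension = NA_character_, conf_level = 0.95) {
  stopifnot(is.numeric(estimate), length(estimate) == 1L,
            is.numeric(se), length(se) == 1L, se >= 0)
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble(
    estimate = as.numeric(estimate),
    se = as.numeric(se),
    ci_low = estimate - z * se,
    ci_high = estimate + z * se,
    p = as.numeric(p),
    n_obs = as.integer(n_obs),
    method = method,
    study = study,
    dimension = dimension
  )
}
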