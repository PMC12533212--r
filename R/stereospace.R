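#' Groups in the 4D competence-warmth space
#'
#' Each social group (and the AI category itself) is located by four
#' association effects: competence and warmth measured with each of two
#' attribute dictionaries. The coordinates are assembled in the canonical
#' order (competence/dictionary A, warmth/A, competence/B, warmth/B)
#' regardless of input order.
#'
#' @param group Group label (e.g. `"AI"`, `"men"`, `"poor"`).
#' @param assoc A named list or named numeric vector with exactly the
#'   elements `comp_a`, `warm_a`, `comp_b`, `warm_b`.
#' @param method `"scweat"` or `"fmat"` (points are only comparable within a
#'   method).
#' @param status `"advantaged"`, `"disadvantaged"` or `"none"` (AI carries
#'   `"none"`).
#' @return An object of class `stereotype_point` with fields `group`,
#'   `method`, `coords` (named length-4 vector), `status`.
#' @export
#'
#' @examples
#' build_point("men", c(comp_a = 0.1, warm_a = 0.2, comp_b = 0.3,
#'                      warm_b = 0.4), "scweat", "advantaged")
build_point <- function(group, assoc, method = c("scweat", "fmat"),
                        status = c("none", "advantaged", "disadvantaged")) {
  method <- match.arg(method)
  status <- match.arg(status)
  dims <- c("comp_a", "warm_a", "comp_b", "warm_b")
  assoc <- unlist(assoc)
  extra <- setdiff(names(assoc), dims)
  missing <- setdiff(dims, names(assoc))
  if (length(extra) > 0L || length(missing) > 0L) {
    stop_stereolang(
      "stereolang_schema_error",
      sprintf("point '%s' needs exactly dimensions %s%s%s", group,
              paste(dims, collapse = ", "),
              if (length(missing)) paste0("; missing: ",
                                          paste(missing, collapse = ", "))
              else "",
              if (length(extra)) paste0("; unknown: ",
                                        paste(extra, collapse = ", "))
              else ""))
  }
  coords <- as.numeric(assoc[dims])
  if (any(!is.finite(coords))) {
    stop_stereolang("stereolang_content_error",
                    sprintf("point '%s' has non-finite coordinates", group))
  }
  structure(list(group = group, method = method,
                 coords = setNames(coords, dims), status = status),
            class = "stereotype_point")
}

#' @export
print.stereotype_point <- function(x, ...) {
  cat(sprintf("<stereotype_point '%s'> method=%s status=%s (%s)\n",
              x$group, x$method, x$status,
              paste(sprintf("%s=%.3f", names(x$coords), x$coords),
                    collapse = ", ")))
  invisible(x)
}

#' Euclidean distance between two stereotype points
#'
#' Points must come from the same measurement method (SC-WEAT distances and
#' FMAT distances live on different scales and are only pooled downstream
#' through the method fixed effect of [advantaged_contrast()]).
#'
#' @param a,b `stereotype_point`s with the same `method`.
#' @return Non-negative scalar `sqrt(sum((a - b)^2))`.
#' @export
euclidean_distance <- function(a, b) {
  stopifnot(inherits(a, "stereotype_point"), inherits(b, "stereotype_point"))
  if (!identical(a$method, b$method)) {
    stop_stereolang("stereolang_comparability_error",
                    "points from different methods are not comparable")
  }
  sqrt(sum((a$coords - b$coords)^2))
}

#' Distances from a reference point to a set of group points
#'
#' @param reference The reference `stereotype_point` (typically AI).
#' @param points List of `stereotype_point`s (same method as `reference`).
#' @return A tibble of distance records: `group`, `method`, `distance`,
#'   `status`.
#' @export
distance_records <- function(reference, points) {
  dplyr::bind_rows(lapply(points, function(p) {
    tibble(group = p$group, method = p$method,
           distance = euclidean_distance(reference, p), status = p$status)
  }))
}

#' Advantaged-versus-disadvantaged distance contrast
#'
#' OLS of distance on a status indicator (disadvantaged = 1) with a method
#' fixed effect absorbing the scale difference between SC-WEAT and FMAT. A
#' positive slope means disadvantaged groups lie farther from the reference
#' point, i.e. AI sits closer to advantaged groups.
#'
#' @param records A tibble from [distance_records()] (one or both methods,
#'   both statuses present).
#' @return An [effect_estimate()] row for the status slope.
#' @export
advantaged_contrast <- function(records) {
  stopifnot(all(c("distance", "status", "method") %in% names(records)))
  records <- dplyr::filter(records, .data$status != "none")
  if (length(unique(records$status)) < 2L) {
    stop_stereolang("stereolang_design_error",
                    "both advantaged and disadvantaged groups are required")
  }
  records$disadv <- as.integer(records$status == "disadvantaged")
  fit <- if (length(unique(records$method)) > 1L) {
    lm(distance ~ disadv + method, data = records)
  } else {
    lm(distance ~ disadv, data = records)
  }
  # degenerate inputs (e.g. perfectly separated toy distances) fit exactly;
  # the perfect-fit warning is uninformative there
  sm <- suppressWarnings(summary(fit))$coefficients
  se <- sm["disadv", "Std. Error"]
  p <- sm["disadv", "Pr(>|t|)"]
  effect_estimate(estimate = sm["disadv", "Estimate"],
                  se = if (is.nan(se)) 0 else se,
                  p = if (is.nan(p)) NA_real_ else p,
                  n_obs = nrow(records), method = "stereospace")
}
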