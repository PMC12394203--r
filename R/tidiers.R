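#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a CDR3 conformation classification
#'
#' @param x A `cdr3_conformation` from [classify_conformation()].
#' @param ... Unused.
#' @return Tibble with one row per classified value: `value`, `label`.
#' @export
tidy.cdr3_conformation <- function(x, ...) {
  tibble::tibble(value = x$values, label = x$labels)
}

#' One-row summary of a CDR3 conformation classification
#'
#' @inheritParams tidy.cdr3_conformation
#' @return Tibble with `threshold`, `n`, `n_bent`, `n_extended`,
#'   `unimodal`.
#' @export
glance.cdr3_conformation <- function(x, ...) {
  tibble::tibble(
    threshold = x$threshold,
    n = length(x$values),
    n_bent = sum(x$labels == "bent"),
    n_extended = sum(x$labels == "extended"),
    unimodal = x$unimodal
  )
}

#' Tidy a binned-mean regression
#'
#' @param x A `binned_regression` from [binned_mean_regression()].
#' @param ... Unused.
#' @return The coefficient table of the underlying OLS fit on bin means.
#' @export
tidy.binned_regression <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std.error = sm[, "Std. Error"],
    statistic = sm[, "t value"],
    p.value = sm[, "Pr(>|t|)"]
  )
}

#' One-row summary of a binned-mean regression
#'
#' @inheritParams tidy.binned_regression
#' @return Tibble with `slope`, `intercept`, `n_bins`, `r.squared`.
#' @export
glance.binned_regression <- function(x, ...) {
  tibble::tibble(
    slope = x$slope,
    intercept = x$intercept,
    n_bins = nrow(x$bins),
    r.squared = summary(x$fit)$r.squared
  )
}
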