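#' Pearson correlation with a two-sided significance test
#'
#' Pearson's r with the two-sided p-value from the t approximation
#' (`stats::cor.test`). Pairs with a missing entry in either vector are
#' dropped pairwise; zero variance in either variable yields a missing `r` rather
#' than an error.
#'
#' @param x,y Numeric vectors of equal length.
#' @return One-row tibble with `r`, `p`, `n` (pairs used).
#' @export
pearson_with_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(r = NA_real_, p = NA_real_, n = n))
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Two-tailed Mann-Whitney U test
#'
#' The U statistic for sample `a` versus `b` with a two-sided p-value:
#' exact enumeration when both samples are small (min n <= 8) and untied,
#' the tie-corrected normal approximation otherwise
#' (via `stats::wilcox.test`).
#'
#' @param a,b Nonempty numeric vectors.
#' @return One-row tibble with `U` (for `a` vs `b`) and `p`.
#' @export
mann_whitney_u <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- min(length(a), length(b)) <= 8 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = exact, correct = !exact)
  )
  tibble::tibble(U = unname(wt$statistic), p = min(wt$p.value, 1))
}

#' F statistic for comparing two standard deviations
#'
#' `F = std1^2 / std2^2` with the numerator as given by the caller (no
#' automatic reordering), and a two-sided p-value from the F distribution
#' with `(n1 - 1, n2 - 1)` degrees of freedom computed as
#' `2 * min(tail, 1 - tail)`.
#'
#' @param std1,std2 Positive standard deviations.
#' @param n1,n2 Sample sizes (at least 2).
#' @return One-row tibble with `F`, `p`, `df1`, `df2`.
#' @export
f_variance_ratio <- function(std1, n1, std2, n2) {
  if (std1 <= 0 || std2 <= 0) stop("standard deviations must be > 0",
                                   call. = FALSE)
  stopifnot(n1 >= 2, n2 >= 2)
  f <- std1^2 / std2^2
  tail <- stats::pf(f, n1 - 1, n2 - 1)
  tibble::tibble(F = f, p = min(1, 2 * min(tail, 1 - tail)),
                 df1 = n1 - 1, df2 = n2 - 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment (`stats::p.adjust(method = "BH")`) with
#' input validation; `NA` entries pass through as `NA`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, order-preserving.
#' @export
bh_fdr <- function(p) {
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) {
    stop("p-values outside [0, 1]: ",
         paste(utils::head(p[bad], 5), collapse = ", "), call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Significance star codes
#'
#' Maps p-values to the usual star shorthand: `ns` for p > 0.05,
#' `*` for (0.01, 0.05], `**` for \[0.001, 0.01\], `***` for
#' \[0.0001, 0.001), `****` for p <= 0.0001. The boundary at exactly 0.01
#' falls in `**`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Character vector of star codes (`NA` for `NA` input).
#' @export
stars <- function(p) {
  out <- rep(NA_character_, length(p))
  ok <- !is.na(p)
  out[ok & p > 0.05] <- "ns"
  out[ok & p > 0.01 & p <= 0.05] <- "*"
  out[ok & p >= 0.001 & p <= 0.01] <- "**"
  out[ok & p >= 0.0001 & p < 0.001] <- "***"
  out[ok & p <= 0.0001] <- "****"
  out
}

#' Regression of per-length bin means
#'
#' For presentation-style trend lines: groups `y` by integer `x` (CDR3
#' length), computes per-bin means and standard errors, and fits an ordinary
#' least-squares line through the (length, bin mean) pairs, unweighted.
#' Correlation inference should use all data points
#' ([pearson_with_test()]); this regression is the companion line through
#' bin means.
#'
#' @param x Integer-valued vector (e.g. CDR3 lengths).
#' @param y Numeric response of the same length.
#' @return An object of class `binned_regression`: a list with `slope`,
#'   `intercept`, `bins` (tibble `x`, `n`, `mean`, `se`), and the underlying
#'   `lm` fit. Has [tidy()][generics::tidy] and
#'   [glance()][generics::glance] methods and an `autoplot()`.
#' @export
binned_mean_regression <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  bins <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(x = x, y = y), x),
    n = dplyr::n(),
    mean = mean(y),
    se = stats::sd(y) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  if (nrow(bins) < 3) stop("need >= 3 distinct x values", call. = FALSE)
  fit <- stats::lm(mean ~ x, data = bins)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    bins = bins,
    fit = fit
  ), class = "binned_regression")
}

#' @export
print.binned_regression <- function(x, ...) {
  cat(sprintf("binned mean regression: slope %.4g, intercept %.4g over %d bins\n",
              x$slope, x$intercept, nrow(x$bins)))
  invisible(x)
}

#' Assemble a correlation report with FDR control and star codes
#'
#' Takes a tibble of per-feature Pearson results (columns `r`, `p`, `n` plus
#' any identifier columns), applies Benjamini-Hochberg adjustment across all
#' rows with a non-missing raw p, and appends star codes for the adjusted
#' p-values.
#'
#' @param tbl A tibble containing columns `r`, `p`, `n`.
#' @return The same tibble with `p_adj` and `stars` columns appended.
#' @export
correlation_report <- function(tbl) {
  stopifnot(all(c("r", "p", "n") %in% names(tbl)))
  tbl$p_adj <- bh_fdr(tbl$p)
  tbl$stars <- stars(tbl$p_adj)
  tbl
}
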