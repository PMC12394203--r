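unnest_numbering <- function(x) {
  num <- x$numbering
  lens <- vapply(num, nrow, integer(1))
  tibble::tibble(
    .row = rep(seq_along(num), lens),
    position = unlist(lapply(num, `[[`, "position"), use.names = FALSE),
    insertion = unlist(lapply(num, `[[`, "insertion"), use.names = FALSE),
    residue = unlist(lapply(num, `[[`, "residue"), use.names = FALSE)
  )
}

#' Regional residue usage versus CDR3 length
#'
#' For each of the 20 standard residues, the per-sequence frequency of the
#' residue within the chosen region is correlated (Pearson) with CDR3 length
#' across the repertoire, with Benjamini-Hochberg adjustment over the 20
#' tests. Members whose region slice is empty are dropped for that region.
#'
#' @param x A filtered `vhh_repertoire` with at least 3 distinct CDR3
#'   lengths.
#' @param region Region label as in [region_slice()].
#' @param regions Region boundary table.
#' @return Correlation report tibble: `region`, `residue`, `n`, `r`, `p`,
#'   `p_adj`, `stars`. Residues with zero frequency variance report a missing `r`.
#' @export
regional_usage_vs_length <- function(x, region, regions = imgt_regions()) {
  sq <- region_slice(x, region, regions)
  keep <- nchar(sq) > 0
  if (!any(keep)) {
    return(correlation_report(tibble::tibble(
      region = character(), residue = character(),
      n = integer(), r = numeric(), p = numeric())))
  }
  sq <- sq[keep]
  len <- x$cdr3_length[keep]
  if (length(unique(len)) < 3) {
    stop("need >= 3 distinct CDR3 lengths", call. = FALSE)
  }
  width <- nchar(sq)
  rows <- lapply(AA_STANDARD, function(aa) {
    freq <- stringr::str_count(sq, stringr::fixed(aa)) / width
    ct <- pearson_with_test(freq, len)
    tibble::tibble(region = region, residue = aa,
                   n = ct$n, r = ct$r, p = ct$p)
  })
  correlation_report(dplyr::bind_rows(rows))
}

#' Per-position residue usage versus CDR3 length
#'
#' For every (IMGT position, residue) cell within the chosen region, the
#' presence/absence indicator of that residue at that position is correlated
#' (Pearson) with CDR3 length across the sequences occupying the position.
#' Positions occupied by fewer than `min_n` sequences are masked;
#' single-residue positions report a missing `r` (zero variance). BH adjustment
#' is applied over the whole matrix of tested cells.
#'
#' @inheritParams regional_usage_vs_length
#' @param min_n Minimum number of sequences occupying a position for it to
#'   be tested (default 100; use smaller values for small test sets).
#' @return Correlation report tibble: `region`, `position`, `insertion`,
#'   `residue`, `n`, `r`, `p`, `p_adj`, `stars`.
#' @export
positional_usage_vs_length <- function(x, region, min_n = 100,
                                       regions = imgt_regions()) {
  row <- regions[regions$region == region, ]
  if (nrow(row) != 1) stop("unknown region: ", region, call. = FALSE)
  long <- unnest_numbering(x)
  long <- long[long$position >= row$start & long$position <= row$end, ]
  if (nrow(long) == 0) {
    return(correlation_report(tibble::tibble(
      region = character(), position = integer(), insertion = character(),
      residue = character(), n = integer(), r = numeric(), p = numeric())))
  }
  len <- x$cdr3_length
  if (length(unique(len)) < 3) {
    stop("need >= 3 distinct CDR3 lengths", call. = FALSE)
  }
  key <- paste0(long$position, long$insertion)
  groups <- split(seq_len(nrow(long)), key)
  rows <- purrr::map(groups, function(ix) {
    occ <- long$.row[ix]
    if (length(occ) < min_n) return(NULL)
    res <- long$residue[ix]
    l <- len[occ]
    purrr::map(unique(res), function(aa) {
      ct <- pearson_with_test(as.numeric(res == aa), l)
      tibble::tibble(region = region,
                     position = long$position[ix][1],
                     insertion = long$insertion[ix][1],
                     residue = aa, n = ct$n, r = ct$r, p = ct$p)
    }) |> dplyr::bind_rows()
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(region = character(), position = integer(),
                          insertion = character(), residue = character(),
                          n = integer(), r = numeric(), p = numeric())
  }
  out <- dplyr::arrange(out, .data$position, .data$insertion, .data$residue)
  correlation_report(out)
}

#' Germline-linked CDR3 length preference
#'
#' Per-germline CDR3 length summaries plus pairwise two-tailed Mann-Whitney
#' U tests with Benjamini-Hochberg correction across all pairs. Germlines
#' with fewer than 2 members are summarised but excluded from testing with
#' a warning.
#'
#' @param x A `vhh_repertoire` with germline labels on at least two
#'   germlines.
#' @return A list with `summary` (tibble `germline`, `n`, `mean`, `std`) and
#'   `tests` (tibble `germline_a`, `germline_b`, `U`, `p`, `p_adj`,
#'   `stars`).
#' @export
germline_length_preference <- function(x) {
  lab <- x$germline
  ok <- !is.na(lab) & lab != ""
  if (!any(ok)) stop("no germline labels present", call. = FALSE)
  lab <- lab[ok]
  len <- x$cdr3_length[ok]
  if (length(unique(lab)) < 2) {
    stop("need germline labels for >= 2 germlines", call. = FALSE)
  }
  summary <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(germline = lab, len = len), germline),
    n = dplyr::n(), mean = mean(len), std = stats::sd(len),
    .groups = "drop"
  )
  testable <- summary$germline[summary$n >= 2]
  if (length(testable) < nrow(summary)) {
    warning("germline(s) with n < 2 excluded from testing: ",
            paste(setdiff(summary$germline, testable), collapse = ", "),
            call. = FALSE)
  }
  tests <- NULL
  if (length(testable) >= 2) {
    pairs <- utils::combn(sort(testable), 2)
    tests <- purrr::map(seq_len(ncol(pairs)), function(k) {
      a <- pairs[1, k]; b <- pairs[2, k]
      mw <- mann_whitney_u(len[lab == a], len[lab == b])
      tibble::tibble(germline_a = a, germline_b = b, U = mw$U, p = mw$p)
    }) |> dplyr::bind_rows()
    tests$p_adj <- bh_fdr(tests$p)
    tests$stars <- stars(tests$p_adj)
  } else {
    tests <- tibble::tibble(germline_a = character(), germline_b = character(),
                            U = numeric(), p = numeric(), p_adj = numeric(),
                            stars = character())
  }
  list(summary = summary, tests = tests)
}
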