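# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

imgt_loop_positions <- function(start, end, len) {
  stopifnot(len <= end - start + 1)
  left <- ceiling(len / 2)
  right <- len - left
  as.integer(c(seq(start, length.out = left),
               if (right > 0) seq(end - right + 1, end) else integer()))
}

# Calibrate the pre-truncation normal so that the discretized, >= 5 truncated
# germline mixture realizes the recipe's nominal CDR3 length mean and std.
calibrate_length_model <- function(length_mean, length_std, shifts, weights,
                                   min_len = 5) {
  grid <- min_len:80
  moments <- function(par) {
    mu <- par[1]; s <- exp(par[2])
    p <- rep(0, length(grid))
    for (g in seq_along(shifts)) {
      p <- p + weights[g] * (stats::pnorm(grid + 0.5, mu + shifts[g], s) -
                               stats::pnorm(grid - 0.5, mu + shifts[g], s))
    }
    p <- p / sum(p)
    m <- sum(grid * p)
    v <- sum(grid^2 * p) - m^2
    c(m, sqrt(v))
  }
  obj <- function(par) {
    ms <- moments(par)
    (ms[1] - length_mean)^2 + (ms[2] - length_std)^2
  }
  shift_var <- sum(weights * shifts^2) - sum(weights * shifts)^2
  s0 <- sqrt(max(length_std^2 - shift_var, 0.25))
  fit <- stats::optim(c(length_mean, log(s0)), obj,
                      control = list(reltol = 1e-10, maxit = 500))
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

default_germlines <- function() {
  tibble::tibble(
    name = c("IGHV3-short", "IGHV3-long", "IGHV3-mid"),
    weight = c(0.4, 0.4, 0.2),
    length_shift = c(-2.2, 2.2, 0),
    # hallmark residues (IMGT position -> residue)
    res35 = c("S", "D", "S"),    # CDR1: acidic D in the long-CDR3 germline
    res36 = c("I", "Y", "A"),
    res37 = c("I", "Y", "A"),
    res39 = c("Q", "I", "Q"),
    res42 = c("Y", "F", "Y"),    # the Y/F switch at IMGT 42
    res49 = c("Q", "E", "A"),    # acidic E in FR2 of the long-CDR3 germline
    res52 = c("L", "G", "L"),
    res55 = c("S", "C", "S"),
    res62 = c("S", "D", "S"),    # acidic D in CDR2 of the long-CDR3 germline
    p_n105 = c(0.65, 0.10, 0.35) # germline-linked N at CDR3 position 105
  )
}

cdr3_background <- function() {
  # Background CDR3 composition. Charge-balanced by construction:
  # P(D) + P(E) equals P(K) + P(R) + 0.1 * P(H), so with no planted slope the
  # expected CDR3 charge is independent of length.
  p <- c(A = 0.070, R = 0.047, N = 0.045, D = 0.050, C = 0.020,
         Q = 0.030, E = 0.050, G = 0.110, H = 0.030, I = 0.030,
         L = 0.050, K = 0.050, M = 0.010, F = 0.040, P = 0.030,
         S = 0.100, T = 0.060, W = 0.025, Y = 0.110, V = 0.043)
  p / sum(p)
}

#' Recipe for a synthetic VHH repertoire
#'
#' Defines the statistical structure of a generated repertoire: the
#' species-level CDR3 length distribution (discretized normal truncated at
#' 5), germline profiles with length preferences and hallmark residues
#' (including the Y/F switch at IMGT 42), a planted acidic-substitution
#' slope making longer CDR3s more negatively charged, CDR3 cysteine
#' enrichment and position-105 asparagine depletion with length, a read
#' count distribution, and duplicate/outlier injection rates.
#'
#' Defaults emulate a filtered alpaca repertoire: length mean 15.73,
#' std 4.61, truncated at 5.
#'
#' @param n Number of members to draw (default 10000).
#' @param species Species label (default `"alpaca"`).
#' @param length_mean,length_std Target CDR3 length mean and standard
#'   deviation of the emitted repertoire.
#' @param germlines Germline profile tibble (see `default_germlines` in the
#'   package sources for the shape); weights must sum to 1.
#' @param charge_slope Per-length-unit increase in the CDR3 acidic
#'   substitution probability (default 0.008); 0 plants no charge-length
#'   effect.
#' @param c_enrich_slope Per-length-unit increase in CDR3 cysteine
#'   probability (default 0.004).
#' @param n105_decay Logistic decay rate of N usage at position 105 with
#'   length (default 0.25); 0 plants no site effect.
#' @param count_mu,count_size Negative-binomial read count parameters
#'   (counts are `1 + rnbinom`).
#' @param duplicate_rate Fraction of additional rows that duplicate an
#'   existing amino-acid sequence (default 0.05).
#' @param outlier_rate Fraction of members drawn with an extreme CDR3
#'   length (default 0.003), for the z-filter to remove.
#' @param seed Integer RNG seed.
#' @return A list of class `repertoire_recipe`.
#' @export
repertoire_recipe <- function(n = 10000, species = "alpaca",
                              length_mean = 15.73, length_std = 4.61,
                              germlines = default_germlines(),
                              charge_slope = 0.008,
                              c_enrich_slope = 0.004,
                              n105_decay = 0.25,
                              count_mu = 10, count_size = 1.2,
                              duplicate_rate = 0.05,
                              outlier_rate = 0.003,
                              seed = 1L) {
  if (length_mean < 5) stop("length_mean must be >= 5", call. = FALSE)
  if (length_std <= 0) stop("length_std must be > 0", call. = FALSE)
  if (abs(sum(germlines$weight) - 1) > 1e-8) {
    stop("germline weights must sum to 1", call. = FALSE)
  }
  structure(list(
    n = n, species = species, length_mean = length_mean,
    length_std = length_std, germlines = germlines,
    charge_slope = charge_slope, c_enrich_slope = c_enrich_slope,
    n105_decay = n105_decay, count_mu = count_mu, count_size = count_size,
    duplicate_rate = duplicate_rate, outlier_rate = outlier_rate,
    seed = as.integer(seed)
  ), class = "repertoire_recipe")
}

# Framework/CDR templates (fixed scaffolds with light composition noise).
FR1_TEMPLATE <- "QVQLVESGGGLVQAGGSLRLSCAASG"          # IMGT 1-26
FR2_TEMPLATE <- "MGWYRQAPGKQRELVAA"                   # IMGT 39-55
FR3_TEMPLATE <- "DSVKGRFTISRDNAKNTVYLQMNSLKPEDTAVYYCAARS" # IMGT 66-104 (39)
FR4_TEMPLATE <- "WGQGTQVTVSS"                         # IMGT 118-128
CDR1_TEMPLATE <- "RTFSSYAM"                           # 8 residues
CDR2_TEMPLATE <- "ISWSGGST"                           # 8 residues

mutate_template <- function(mat, rate) {
  if (rate <= 0) return(mat)
  hit <- which(stats::runif(length(mat)) < rate)
  mat[hit] <- sample(AA_STANDARD, length(hit), replace = TRUE)
  mat
}

#' Generate a synthetic annotated VHH repertoire
#'
#' Draws a repertoire under a [repertoire_recipe()]: CDR3 lengths from a
#' discretized germline-shifted normal truncated at 5 (calibrated so the
#' emitted lengths hit the recipe's nominal mean/std), germlines chosen by
#' weight fixing hallmark framework/CDR1 residues, CDR3 composition with
#' the planted acidic slope, cysteine enrichment and position-105 N
#' depletion, negative-binomial read counts, and injected amino-acid
#' duplicates and length outliers. Deterministic given the recipe seed.
#'
#' @param recipe A [repertoire_recipe()].
#' @param dir Optional directory; when given, writes `repertoire.tsv` (the
#'   dialect [read_repertoire()] ingests) and `ground_truth.json`.
#' @return A `vhh_repertoire` with a `ground_truth` attribute describing
#'   every planted effect.
#' @export
simulate_repertoire <- function(recipe, dir = NULL) {
  stopifnot(inherits(recipe, "repertoire_recipe"))
  with_seed(recipe$seed, {
    g <- recipe$germlines
    n <- recipe$n

    cal <- calibrate_length_model(recipe$length_mean, recipe$length_std,
                                  g$length_shift, g$weight)

    gl_idx <- sample(nrow(g), n, replace = TRUE, prob = g$weight)
    is_outlier <- stats::runif(n) < recipe$outlier_rate
    len <- integer(n)
    todo <- rep(TRUE, n)
    while (any(todo)) {
      raw <- stats::rnorm(sum(todo), cal$mu + g$length_shift[gl_idx[todo]],
                          cal$sigma)
      len[todo] <- as.integer(round(raw))
      todo[todo] <- len[todo] < 5
    }
    len[is_outlier] <- as.integer(round(
      recipe$length_mean +
        recipe$length_std * stats::runif(sum(is_outlier), 3.2, 5)))

    # fixed-length segments as character matrices with light noise
    seg <- function(template, rate) {
      mat <- matrix(strsplit(template, "")[[1]], nrow = n,
                    ncol = nchar(template), byrow = TRUE)
      mutate_template(mat, rate)
    }
    fr1 <- seg(FR1_TEMPLATE, 0.02)
    cdr1 <- seg(CDR1_TEMPLATE, 0.10)
    fr2 <- seg(FR2_TEMPLATE, 0.03)
    cdr2 <- seg(CDR2_TEMPLATE, 0.10)
    fr3 <- seg(FR3_TEMPLATE, 0.02)
    fr4 <- seg(FR4_TEMPLATE, 0.01)

    # germline hallmark residues (positions within their segment layouts)
    cdr1_pos <- imgt_loop_positions(27, 38, ncol(cdr1))
    cdr2_pos <- imgt_loop_positions(56, 65, ncol(cdr2))
    put <- function(mat, pos_vec, imgt, values) {
      j <- match(imgt, pos_vec)
      if (!is.na(j)) mat[, j] <- values
      mat
    }
    cdr1 <- put(cdr1, cdr1_pos, 35, g$res35[gl_idx])
    cdr1 <- put(cdr1, cdr1_pos, 36, g$res36[gl_idx])
    cdr1 <- put(cdr1, cdr1_pos, 37, g$res37[gl_idx])
    fr2 <- put(fr2, 39:55, 39, g$res39[gl_idx])
    fr2 <- put(fr2, 39:55, 42, g$res42[gl_idx])
    fr2 <- put(fr2, 39:55, 49, g$res49[gl_idx])
    fr2 <- put(fr2, 39:55, 52, g$res52[gl_idx])
    fr2 <- put(fr2, 39:55, 55, g$res55[gl_idx])
    cdr2 <- put(cdr2, cdr2_pos, 62, g$res62[gl_idx])

    # CDR3: per-length composition with planted effects
    bg <- cdr3_background()
    comp_for_length <- function(L) {
      p <- bg
      dlt <- recipe$charge_slope * (L - recipe$length_mean)
      dC <- recipe$c_enrich_slope * (L - recipe$length_mean)
      p["D"] <- max(p["D"] + dlt / 2, 0.001)
      p["E"] <- max(p["E"] + dlt / 2, 0.001)
      p["C"] <- max(p["C"] + dC, 0.001)
      # re-balance on the neutral pool so probabilities stay a simplex
      pool <- c("G", "S", "T", "A")
      excess <- sum(p) - 1
      p[pool] <- pmax(p[pool] - excess / length(pool), 0.001)
      p / sum(p)
    }
    cdr3 <- vector("list", n)
    for (L in sort(unique(len))) {
      members <- which(len == L)
      p <- comp_for_length(L)
      draws <- sample(AA_STANDARD, length(members) * L, replace = TRUE,
                      prob = p)
      m <- matrix(draws, nrow = length(members), ncol = L)
      # germline- and length-linked N at position 105 (first CDR3 column)
      p_n <- stats::plogis(stats::qlogis(g$p_n105[gl_idx[members]]) -
                             recipe$n105_decay * (L - recipe$length_mean))
      put_n <- stats::runif(length(members)) < p_n
      m[put_n, 1] <- "N"
      for (k in seq_along(members)) cdr3[[members[k]]] <- m[k, ]
    }

    # assemble numbering and sequences
    pre_pos <- c(1:26, cdr1_pos, 39:55, cdr2_pos, 66:104)
    post_pos <- 118:128
    numbering <- vector("list", n)
    sequence <- character(n)
    cdr3_pos_cache <- list()
    for (i in seq_len(n)) {
      L <- len[i]
      key <- as.character(L)
      if (is.null(cdr3_pos_cache[[key]])) {
        cdr3_pos_cache[[key]] <- imgt_cdr3_positions(L)
      }
      cp <- cdr3_pos_cache[[key]]
      res <- c(fr1[i, ], cdr1[i, ], fr2[i, ], cdr2[i, ], fr3[i, ],
               cdr3[[i]], fr4[i, ])
      pos <- c(pre_pos, cp$position, post_pos)
      ins <- c(rep("", length(pre_pos)), cp$insertion,
               rep("", length(post_pos)))
      numbering[[i]] <- data.frame(position = pos, insertion = ins,
                                   residue = res, stringsAsFactors = FALSE)
      sequence[i] <- paste(res, collapse = "")
    }

    count <- 1L + stats::rnbinom(n, size = recipe$count_size,
                                 mu = recipe$count_mu)
    tbl <- tibble::tibble(
      id = sprintf("seq%06d", seq_len(n)),
      species = recipe$species,
      sequence = sequence,
      count = as.integer(count),
      germline = g$name[gl_idx],
      numbering = numbering,
      cdr3_length = len
    )

    n_dup <- stats::rbinom(1, n, recipe$duplicate_rate)
    dup_ids <- character(0)
    if (n_dup > 0) {
      src <- sample(n, n_dup, replace = TRUE)
      dup <- tbl[src, ]
      dup$id <- sprintf("dup%06d", seq_len(n_dup))
      dup$count <- 1L + stats::rnbinom(n_dup, size = recipe$count_size,
                                       mu = recipe$count_mu)
      dup_ids <- dup$id
      tbl <- dplyr::bind_rows(tbl, dup)
    }

    out <- new_vhh_repertoire(tbl)
    attr(out, "ground_truth") <- list(
      recipe = recipe,
      length_model = cal,
      outlier_ids = tbl$id[seq_len(n)][is_outlier],
      duplicate_ids = dup_ids,
      planted = list(
        charge_slope = recipe$charge_slope,
        c_enrich_slope = recipe$c_enrich_slope,
        n105_decay = recipe$n105_decay,
        res42_by_germline = stats::setNames(g$res42, g$name),
        length_shift_by_germline = stats::setNames(g$length_shift, g$name)
      )
    )
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      write_repertoire(out, file.path(dir, "repertoire.tsv"))
      gt <- attr(out, "ground_truth")
      gt$recipe <- unclass(gt$recipe)
      gt$recipe$germlines <- as.data.frame(gt$recipe$germlines)
      jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
    }
    out
  })
}
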