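#' Run the repertoire branch of the analysis
#'
#' End-to-end sequence-level analysis of one or more repertoires: the
#' three-stage filter, CDR3 length summaries, cross-species comparisons
#' (variance-ratio F tests and Mann-Whitney U on lengths), per-region
#' charge/hydropathy correlations with CDR3 length, regional and
#' per-position residue usage correlations, and germline length preference
#' where labels exist. All correlation families are BH-adjusted within
#' their report.
#'
#' @param x A `vhh_repertoire` or a named list of them (one per species
#'   group).
#' @param min_count,z_max Filter parameters (see [filter_repertoire()]).
#' @param usage_regions Regions for residue-usage correlation (default
#'   CDR1, FR2, CDR3).
#' @param min_position_n Occupancy threshold for positional usage.
#' @param regions Region boundary table.
#' @return A list of class `cdr3_repertoire_report` with elements
#'   `length_summary`, `cross_species`, `feature_correlations`,
#'   `regional_usage`, `positional_usage`, `germline`, `filter_logs`,
#'   `features`, and `manifest`.
#' @export
run_repertoire_branch <- function(x, min_count = 5, z_max = 2.5,
                                  usage_regions = c("CDR1", "FR2", "CDR3"),
                                  min_position_n = 100,
                                  regions = imgt_regions()) {
  reps <- if (inherits(x, "vhh_repertoire")) list(x) else x
  if (length(reps) == 0 || any(!vapply(reps, inherits, logical(1),
                                       "vhh_repertoire"))) {
    stop("input must be a vhh_repertoire or a list of them", call. = FALSE)
  }
  if (any(vapply(reps, nrow, integer(1)) == 0)) {
    stop("empty input repertoire", call. = FALSE)
  }
  if (is.null(names(reps))) {
    names(reps) <- vapply(reps, function(r) r$species[1], character(1))
  }

  filtered <- lapply(reps, filter_repertoire, min_count = min_count,
                     z_max = z_max)
  logs <- lapply(filtered, filter_log)

  lsum <- dplyr::bind_rows(lapply(filtered, length_summary), .id = "group")

  cross <- NULL
  if (length(filtered) >= 2) {
    pairs <- utils::combn(names(filtered), 2)
    cross <- purrr::map(seq_len(ncol(pairs)), function(k) {
      a <- pairs[1, k]; b <- pairs[2, k]
      sa <- lsum[lsum$group == a, ]
      sb <- lsum[lsum$group == b, ]
      fv <- f_variance_ratio(sa$std, sa$count, sb$std, sb$count)
      mw <- mann_whitney_u(filtered[[a]]$cdr3_length,
                           filtered[[b]]$cdr3_length)
      tibble::tibble(group_a = a, group_b = b,
                     mean_diff = sa$mean - sb$mean,
                     F = fv$F, p_f = fv$p, U = mw$U, p_u = mw$p)
    }) |> dplyr::bind_rows()
    cross$p_u_adj <- bh_fdr(cross$p_u)
    cross$stars <- stars(cross$p_u_adj)
  }

  feats <- lapply(filtered, region_features, regions = regions)

  feat_cor <- purrr::imap(feats, function(ft, grp) {
    cols <- setdiff(names(ft), c("id", "species", "germline", "cdr3_length"))
    rows <- purrr::map(cols, function(cl) {
      ct <- pearson_with_test(ft[[cl]], ft$cdr3_length)
      tibble::tibble(group = grp, feature = cl, n = ct$n, r = ct$r, p = ct$p)
    })
    correlation_report(dplyr::bind_rows(rows))
  }) |> dplyr::bind_rows()

  reg_usage <- purrr::imap(filtered, function(fr, grp) {
    dplyr::bind_rows(lapply(usage_regions, function(rg) {
      regional_usage_vs_length(fr, rg, regions)
    })) |> dplyr::mutate(group = grp, .before = 1)
  }) |> dplyr::bind_rows()

  pos_usage <- purrr::imap(filtered, function(fr, grp) {
    dplyr::bind_rows(lapply(usage_regions, function(rg) {
      positional_usage_vs_length(fr, rg, min_n = min_position_n,
                                 regions = regions)
    })) |> dplyr::mutate(group = grp, .before = 1)
  }) |> dplyr::bind_rows()

  germ <- purrr::imap(filtered, function(fr, grp) {
    has <- any(!is.na(fr$germline) & fr$germline != "")
    if (!has) return(NULL)
    gp <- germline_length_preference(fr)
    list(summary = dplyr::mutate(gp$summary, group = grp, .before = 1),
         tests = dplyr::mutate(gp$tests, group = grp, .before = 1))
  })
  germ <- germ[!vapply(germ, is.null, logical(1))]
  germline <- list(
    summary = dplyr::bind_rows(lapply(germ, `[[`, "summary")),
    tests = dplyr::bind_rows(lapply(germ, `[[`, "tests"))
  )

  structure(list(
    length_summary = lsum,
    cross_species = cross,
    feature_correlations = feat_cor,
    regional_usage = reg_usage,
    positional_usage = pos_usage,
    germline = germline,
    filter_logs = logs,
    features = feats,
    manifest = list(min_count = min_count, z_max = z_max,
                    usage_regions = usage_regions,
                    min_position_n = min_position_n,
                    groups = names(filtered),
                    n_input = vapply(reps, nrow, integer(1)),
                    n_filtered = vapply(filtered, nrow, integer(1)))
  ), class = "cdr3_repertoire_report")
}

#' Per-structure feature table
#'
#' Extracts the structural feature row of each model: CDR3 length, the
#' FR2-CDR3 minimum centroid distance, CDR3 interaction counts with each
#' VHH segment, the interface summary (paratope/epitope sizes, per-segment
#' paratope counts, FR2 involvement, seven-class compositions), CDR3
#' secondary-structure fractions, and optionally SASA, surface
#' hydrophobicity and buried surface areas.
#'
#' @param models List of `vhh_complex` objects.
#' @param ids Optional character ids (default `structure_1` ...).
#' @param threshold Contact threshold in Angstrom (default 4).
#' @param min_epitope Minimum epitope size (default 6).
#' @param compute_sasa Also compute SASA-derived features (default TRUE;
#'   the dominant cost for large sets).
#' @param n_points Shrake-Rupley points per atom (default 960).
#' @return A tibble, one row per structure.
#' @export
structure_features <- function(models, ids = NULL, threshold = 4,
                               min_epitope = 6, compute_sasa = TRUE,
                               n_points = 960) {
  if (is.null(ids)) ids <- sprintf("structure_%d", seq_along(models))
  rows <- purrr::map(seq_along(models), function(i) {
    m <- models[[i]]
    res <- model_residues(m, m$vhh_chain)
    lcdr3 <- sum(!is.na(res$region) & res$region == "CDR3")
    dis <- tryCatch(suppressWarnings(fr2_cdr3_dis(m)),
                    error = function(e) NA_real_)
    prof <- segment_interaction_profile(m, threshold)
    prof_row <- stats::setNames(as.list(prof$n_pairs),
                                paste0("cdr3_contacts_", prof$segment))
    row <- tibble::tibble(id = ids[i], cdr3_length = lcdr3,
                          fr2_cdr3_dis = dis)
    row <- dplyr::bind_cols(row, tibble::as_tibble(prof_row))
    if (length(m$antigen_chains) > 0) {
      row <- dplyr::bind_cols(
        row, interface_summary(m, threshold, min_epitope))
    }
    row <- dplyr::bind_cols(row, ss_usage(m, "CDR3"))
    if (compute_sasa) {
      sa <- sasa_shrake_rupley(m, n_points = n_points, chains = m$vhh_chain)
      row$sasa_total <- sum(sa$sasa)
      row$surface_hydrophobicity <- surface_hydrophobicity(sa)
      if (length(m$antigen_chains) > 0) {
        row <- dplyr::bind_cols(
          row, buried_surface_area(m, n_points = n_points))
      }
    }
    row
  })
  dplyr::bind_rows(rows)
}

#' Run the structure branch of the analysis
#'
#' End-to-end structural analysis of a set of VHH-antigen complexes:
#' sequence-identity redundancy removal, per-structure feature extraction,
#' the epitope-size filter, bent/extended conformation classification from
#' the FR2-CDR3 distance density, and Pearson correlations of every
#' numeric feature with CDR3 length, overall and within the
#' conformation and FR2-involvement strata. Deterministic given the same
#' inputs.
#'
#' @inheritParams structure_features
#' @param min_stratum Minimum stratum size for reported correlations
#'   (default 10); smaller strata are suppressed with a warning.
#' @return A list of class `cdr3_structure_report`: `features` (accepted
#'   structures, with `conformation`), `rejected` (structures failing the
#'   epitope filter), `conformation` (the classifier object, `NULL` if too
#'   few values), `correlations` (long tibble with `group`, `feature`,
#'   `n`, `r`, `p`, `p_adj`, `stars`), and `manifest`.
#' @export
run_structure_branch <- function(models, ids = NULL, threshold = 4,
                                 min_epitope = 6, compute_sasa = TRUE,
                                 n_points = 960, min_stratum = 10) {
  if (length(models) == 0) stop("no structures given", call. = FALSE)
  if (is.null(ids)) ids <- sprintf("structure_%d", seq_along(models))
  seqs <- vapply(models, model_sequence, character(1))
  keep <- !duplicated(seqs)
  models <- models[keep]
  ids <- ids[keep]

  ft <- structure_features(models, ids, threshold, min_epitope,
                           compute_sasa, n_points)
  accepted <- if ("accepted" %in% names(ft)) ft$accepted else
    rep(TRUE, nrow(ft))
  rejected <- ft[!accepted, ]
  ft <- ft[accepted, ]

  conf <- NULL
  vals <- ft$fr2_cdr3_dis
  if (sum(is.finite(vals)) >= 20) {
    conf <- classify_conformation(vals[is.finite(vals)])
    ft$conformation <- NA_character_
    ft$conformation[is.finite(vals)] <- as.character(conf$labels)
  } else {
    ft$conformation <- NA_character_
  }

  cor_group <- function(sub, label) {
    if (nrow(sub) < min_stratum) {
      warning("stratum '", label, "' has fewer than ", min_stratum,
              " structures; correlations suppressed", call. = FALSE)
      return(NULL)
    }
    num_cols <- names(sub)[vapply(sub, is.numeric, logical(1))]
    num_cols <- setdiff(num_cols, "cdr3_length")
    rows <- purrr::map(num_cols, function(cl) {
      ct <- pearson_with_test(sub[[cl]], sub$cdr3_length)
      tibble::tibble(group = label, feature = cl, n = ct$n,
                     r = ct$r, p = ct$p)
    })
    correlation_report(dplyr::bind_rows(rows))
  }

  groups <- list(all = ft)
  if (!all(is.na(ft$conformation))) {
    for (cf in c("bent", "extended")) {
      groups[[cf]] <- ft[!is.na(ft$conformation) & ft$conformation == cf, ]
    }
  }
  if ("fr2_involved" %in% names(ft)) {
    groups[["fr2_involved"]] <- ft[ft$fr2_involved, ]
    groups[["fr2_uninvolved"]] <- ft[!ft$fr2_involved, ]
  }
  correlations <- dplyr::bind_rows(
    purrr::imap(groups, function(sub, label) cor_group(sub, label)))

  structure(list(
    features = ft,
    rejected = rejected,
    conformation = conf,
    correlations = correlations,
    manifest = list(threshold = threshold, min_epitope = min_epitope,
                    compute_sasa = compute_sasa, n_points = n_points,
                    min_stratum = min_stratum,
                    n_input = length(keep), n_nonredundant = sum(keep),
                    n_accepted = nrow(ft), n_rejected = nrow(rejected))
  ), class = "cdr3_structure_report")
}

#' @export
print.cdr3_repertoire_report <- function(x, ...) {
  cat("CDR3 repertoire report:",
      paste(x$manifest$groups, collapse = ", "), "\n")
  print(x$length_summary)
  invisible(x)
}

#' @export
print.cdr3_structure_report <- function(x, ...) {
  cat(sprintf("CDR3 structure report: %d accepted, %d rejected structures\n",
              x$manifest$n_accepted, x$manifest$n_rejected))
  if (!is.null(x$conformation)) print(x$conformation)
  invisible(x)
}
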