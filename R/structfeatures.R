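residue_key <- function(at) paste(at$chain, at$position, at$insertion)

# Unordered chain-order index of every VHH residue (for adjacency exclusion).
vhh_residue_order <- function(m) {
  res <- model_residues(m, m$vhh_chain)
  stats::setNames(seq_len(nrow(res)),
                  paste(res$chain, res$position, res$insertion))
}

min_dist_by_residue <- function(a, b, threshold) {
  # a, b: atom tibbles; returns tibble of residue pairs with any atom pair
  # within threshold, carrying the minimal interatomic distance.
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(tibble::tibble(key_a = character(), key_b = character(),
                          min_dist = numeric()))
  }
  xa <- as.matrix(a[, c("x", "y", "z")])
  xb <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rep(1, nrow(xb))) +
    outer(rep(1, nrow(xa)), rowSums(xb^2)) - 2 * xa %*% t(xb)
  d2[d2 < 0] <- 0
  hit <- which(d2 <= threshold^2, arr.ind = TRUE)
  if (nrow(hit) == 0) {
    return(tibble::tibble(key_a = character(), key_b = character(),
                          min_dist = numeric()))
  }
  ka <- residue_key(a)[hit[, 1]]
  kb <- residue_key(b)[hit[, 2]]
  dd <- sqrt(d2[hit])
  agg <- tapply(dd, paste(ka, kb, sep = "|"), min)
  parts <- strsplit(names(agg), "|", fixed = TRUE)
  tibble::tibble(
    key_a = vapply(parts, `[[`, character(1), 1),
    key_b = vapply(parts, `[[`, character(1), 2),
    min_dist = as.numeric(agg)
  )
}

annotate_keys <- function(tbl, m, side) {
  res <- model_residues(m)
  key <- paste(res$chain, res$position, res$insertion)
  ix <- match(tbl[[paste0("key_", side)]], key)
  tbl[[paste0("chain_", side)]] <- res$chain[ix]
  tbl[[paste0("position_", side)]] <- res$position[ix]
  tbl[[paste0("insertion_", side)]] <- res$insertion[ix]
  tbl[[paste0("residue_", side)]] <- res$residue[ix]
  tbl[[paste0("region_", side)]] <- res$region[ix]
  tbl
}

#' Residue contacts at a distance threshold
#'
#' Residue pairs with any interatomic distance at or below `threshold`
#' (default 4 Angstrom). In `"vhh_antigen"` mode, VHH residues are paired
#' with antigen residues (paratope/epitope contacts). In `"intra_vhh"` mode,
#' VHH residues are paired with each other, excluding self pairs and pairs
#' adjacent in the chain (within +/- 1), each unordered pair reported once.
#'
#' @param m A `vhh_complex`.
#' @param threshold Contact distance in Angstrom (default 4).
#' @param mode `"vhh_antigen"` or `"intra_vhh"`.
#' @return Tibble of contact records with chain/position/insertion/residue/
#'   region for both sides and the minimal interatomic distance `min_dist`.
#' @export
contact_residues <- function(m, threshold = 4,
                             mode = c("vhh_antigen", "intra_vhh")) {
  mode <- match.arg(mode)
  at <- m$atoms
  if (mode == "vhh_antigen") {
    a <- at[at$chain == m$vhh_chain, ]
    b <- at[at$chain %in% m$antigen_chains, ]
    out <- min_dist_by_residue(a, b, threshold)
  } else {
    a <- at[at$chain == m$vhh_chain, ]
    out <- min_dist_by_residue(a, a, threshold)
    ord <- vhh_residue_order(m)
    ia <- ord[out$key_a]
    ib <- ord[out$key_b]
    out <- out[ia < ib - 1, ]
  }
  out <- annotate_keys(out, m, "a")
  out <- annotate_keys(out, m, "b")
  out$key_a <- NULL
  out$key_b <- NULL
  out
}

#' CDR3 interaction profile across VHH segments
#'
#' Counts intra-VHH residue-pair contacts between CDR3 and each other
#' segment (FR1, CDR1, FR2, CDR2, FR3, FR4), plus CDR3-internal pairs
#' (counted once per unordered pair). Sequence-adjacent pairs are excluded
#' as in [contact_residues()].
#'
#' @param m A `vhh_complex`.
#' @param threshold Contact distance in Angstrom (default 4).
#' @return Tibble with columns `segment` and `n_pairs`.
#' @export
segment_interaction_profile <- function(m, threshold = 4) {
  cc <- contact_residues(m, threshold, mode = "intra_vhh")
  segs <- c("FR1", "CDR1", "FR2", "CDR2", "FR3", "FR4", "CDR3")
  counts <- stats::setNames(integer(length(segs)), segs)
  if (nrow(cc) > 0) {
    involves <- cc$region_a == "CDR3" | cc$region_b == "CDR3"
    cc <- cc[involves, ]
    other <- ifelse(cc$region_a == "CDR3" & cc$region_b == "CDR3", "CDR3",
                    ifelse(cc$region_a == "CDR3", cc$region_b, cc$region_a))
    tab <- table(factor(other, levels = segs))
    counts[names(tab)] <- as.integer(tab)
  }
  tibble::tibble(segment = segs, n_pairs = as.integer(counts))
}

residue_centroids <- function(at) {
  heavy <- at[at$element != "H", ]
  key <- residue_key(heavy)
  ukey <- unique(key)
  ix <- match(key, ukey)
  cx <- tapply(heavy$x, ix, mean)
  cy <- tapply(heavy$y, ix, mean)
  cz <- tapply(heavy$z, ix, mean)
  res <- heavy[!duplicated(key), c("chain", "position", "insertion",
                                   "residue", "region")]
  res$cx <- as.numeric(cx)
  res$cy <- as.numeric(cy)
  res$cz <- as.numeric(cz)
  tibble::as_tibble(res)
}

#' Minimum FR2-CDR3 centroid distance (FR2_CDR3_Dis)
#'
#' The conformation metric: centroids (unweighted means of heavy-atom
#' coordinates) are taken for the residue at IMGT position 42 and for each
#' CDR3 residue after excluding the first and last two; the reported value
#' is the minimum Euclidean distance (Angstrom) between the position-42
#' centroid and the trimmed-CDR3 centroids. Low values indicate a CDR3
#' bent down toward FR2.
#'
#' @param m A `vhh_complex`.
#' @return A single numeric distance; `NA` (with a warning) when CDR3 has
#'   fewer than 5 residues so the trimmed set is empty. Missing position 42
#'   is an error.
#' @export
fr2_cdr3_dis <- function(m) {
  cen <- residue_centroids(m$atoms[m$atoms$chain == m$vhh_chain, ])
  p42 <- cen[cen$position == 42, ]
  if (nrow(p42) == 0) stop("position 42 absent from VHH chain",
                           call. = FALSE)
  cdr3 <- cen[!is.na(cen$region) & cen$region == "CDR3", ]
  if (nrow(cdr3) < 5) {
    warning("CDR3 shorter than 5 residues; FR2_CDR3_Dis undefined",
            call. = FALSE)
    return(NA_real_)
  }
  cdr3 <- cdr3[3:(nrow(cdr3) - 2), ]
  d <- sqrt((cdr3$cx - p42$cx[1])^2 + (cdr3$cy - p42$cy[1])^2 +
              (cdr3$cz - p42$cz[1])^2)
  min(d)
}

#' Classify CDR3 conformations from the FR2_CDR3_Dis density
#'
#' Gaussian kernel density estimate (Scott's rule bandwidth, 512-point grid
#' spanning the data range) over a set of FR2_CDR3_Dis values. When the
#' density is bimodal, the threshold is the location of the minimum density
#' between the two highest local maxima; values below the threshold are
#' labelled `bent` (left peak), values at or above it `extended` (right
#' peak). Unimodal densities yield a no-threshold result with a warning and
#' a single-class fallback: all values take the class suggested by the lone
#' peak location relative to `fallback_threshold`.
#'
#' @param values Numeric vector of at least 20 FR2_CDR3_Dis values.
#' @param bw Bandwidth selector passed to [stats::density()] (default
#'   `"nrd"`, Scott's rule).
#' @param grid_n Density grid size (default 512).
#' @param fallback_threshold Distance (Angstrom) deciding the single-class
#'   label on the unimodal path (default 10).
#' @return An object of class `cdr3_conformation`: list with `threshold`
#'   (`NA` if unimodal), `labels` (factor `bent`/`extended`), `values`,
#'   `density` (tibble `x`, `y`), `peaks` (grid locations of the two used
#'   maxima, or one), and `unimodal`. Has `tidy()`, `glance()` and
#'   `autoplot()` methods.
#' @export
classify_conformation <- function(values, bw = "nrd", grid_n = 512,
                                  fallback_threshold = 10) {
  values <- values[is.finite(values)]
  if (length(values) < 20) {
    stop("need >= 20 values for density-based classification", call. = FALSE)
  }
  den <- stats::density(values, bw = bw, n = grid_n,
                        from = min(values), to = max(values))
  y <- den$y
  n <- length(y)
  is_max <- c(y[1] > y[2],
              y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
              y[n] > y[n - 1])
  peaks <- which(is_max)
  if (length(peaks) < 2) {
    warning("density is unimodal; no threshold, single-class labels",
            call. = FALSE)
    peak_x <- if (length(peaks) == 1) den$x[peaks] else mean(values)
    lab <- if (peak_x < fallback_threshold) "bent" else "extended"
    return(structure(list(
      threshold = NA_real_,
      labels = factor(rep(lab, length(values)),
                      levels = c("bent", "extended")),
      values = values,
      density = tibble::tibble(x = den$x, y = den$y),
      peaks = peak_x, unimodal = TRUE
    ), class = "cdr3_conformation"))
  }
  top2 <- peaks[order(-y[peaks])][1:2]
  lo <- min(top2); hi <- max(top2)
  trough <- lo + which.min(y[lo:hi]) - 1
  threshold <- den$x[trough]
  labels <- factor(ifelse(values < threshold, "bent", "extended"),
                   levels = c("bent", "extended"))
  structure(list(
    threshold = threshold, labels = labels, values = values,
    density = tibble::tibble(x = den$x, y = den$y),
    peaks = den$x[sort(top2)], unimodal = FALSE
  ), class = "cdr3_conformation")
}

#' @export
print.cdr3_conformation <- function(x, ...) {
  if (x$unimodal) {
    cat("cdr3_conformation: unimodal density, no threshold;",
        length(x$values), "values labelled", as.character(x$labels[1]), "\n")
  } else {
    cat(sprintf(
      "cdr3_conformation: threshold %.2f A; %d bent, %d extended\n",
      x$threshold, sum(x$labels == "bent"), sum(x$labels == "extended")))
  }
  invisible(x)
}

unit_sphere_points <- function(n) {
  # deterministic golden-section spiral
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Point-sampling SASA: each atom's solvent-accessible sphere (van der
#' Waals radius plus probe) is covered with a deterministic golden-section
#' spiral of `n_points` test points; points not occluded by any neighbour
#' sphere count as accessible, and the per-atom exposed area is summed per
#' residue. Deterministic given the point set.
#'
#' @param x A `vhh_complex` or an atom tibble (as in [vhh_complex()]).
#' @param probe Probe radius in Angstrom (default 1.4, water).
#' @param n_points Test points per atom (default 960).
#' @param radii Named per-element radius table, defaulting to
#'   [element_radii()]. Unknown elements are an error naming the atom.
#' @param chains Optional chain subset to compute on (atoms of other chains
#'   are dropped entirely, i.e. the subset is treated as the molecule).
#' @return Tibble of per-residue SASA (`chain`, `position`, `insertion`,
#'   `residue`, `region`, `sasa` in Angstrom squared).
#' @export
sasa_shrake_rupley <- function(x, probe = 1.4, n_points = 960,
                               radii = element_radii(), chains = NULL) {
  at <- if (inherits(x, "vhh_complex")) x$atoms else tibble::as_tibble(x)
  if (!is.null(chains)) at <- at[at$chain %in% chains, ]
  n <- nrow(at)
  key <- residue_key(at)
  if (n == 0) {
    return(tibble::tibble(chain = character(), position = integer(),
                          insertion = character(), residue = character(),
                          region = character(), sasa = numeric()))
  }
  unknown <- !(at$element %in% names(radii))
  if (any(unknown)) {
    stop("unknown element(s) for SASA radii: ",
         paste(unique(at$element[unknown]), collapse = ", "),
         " (atom ", at$atom_name[which(unknown)[1]], ")", call. = FALSE)
  }
  r <- unname(radii[at$element]) + probe
  xyz <- as.matrix(at[, c("x", "y", "z")])
  pts <- unit_sphere_points(n_points)
  area <- sasa_points_cpp(xyz, r, pts)
  per_res <- tapply(area, factor(key, levels = unique(key)), sum)
  res <- at[!duplicated(key), c("chain", "position", "insertion", "residue")]
  res$region <- if ("region" %in% names(at)) {
    at$region[!duplicated(key)]
  } else {
    NA_character_
  }
  res$sasa <- as.numeric(per_res)
  tibble::as_tibble(res)
}

#' Buried surface area of a VHH-antigen interface
#'
#' SASA lost upon complex formation: the VHH and the antigen are each
#' computed in monomeric form and in the complex, and
#' `interface_bsa = SASA(VHH alone) + SASA(antigen alone) - SASA(complex)`.
#' The per-side values subtract each side's in-complex SASA from its
#' monomeric SASA (`paratope_bsa` for the VHH side, `epitope_bsa` for the
#' antigen side); the two sides sum to the interface total.
#'
#' @param m A `vhh_complex` with at least one antigen chain.
#' @inheritParams sasa_shrake_rupley
#' @return One-row tibble with `interface_bsa`, `paratope_bsa`,
#'   `epitope_bsa` (Angstrom squared).
#' @export
buried_surface_area <- function(m, probe = 1.4, n_points = 960,
                                radii = element_radii()) {
  if (length(m$antigen_chains) == 0) {
    stop("model has no antigen chains", call. = FALSE)
  }
  cx <- sasa_shrake_rupley(m, probe, n_points, radii)
  vhh_alone <- sasa_shrake_rupley(m, probe, n_points, radii,
                                  chains = m$vhh_chain)
  ag_alone <- sasa_shrake_rupley(m, probe, n_points, radii,
                                 chains = m$antigen_chains)
  vhh_in_cx <- sum(cx$sasa[cx$chain == m$vhh_chain])
  ag_in_cx <- sum(cx$sasa[cx$chain %in% m$antigen_chains])
  tibble::tibble(
    interface_bsa = sum(vhh_alone$sasa) + sum(ag_alone$sasa) - sum(cx$sasa),
    paratope_bsa = sum(vhh_alone$sasa) - vhh_in_cx,
    epitope_bsa = sum(ag_alone$sasa) - ag_in_cx
  )
}

#' SASA-weighted surface hydrophobicity
#'
#' Sum over residues of the residue's solvent-accessible surface area
#' multiplied by its hydropathy index: exposed hydrophobic residues raise
#' the score, buried ones do not contribute.
#'
#' @param x A `vhh_complex` (the VHH chain alone is used) or a per-residue
#'   SASA tibble from [sasa_shrake_rupley()].
#' @param scale Hydropathy scale, defaulting to [kyte_doolittle()].
#' @inheritParams sasa_shrake_rupley
#' @return Single numeric score (Angstrom squared times hydropathy units);
#'   0 for an empty model.
#' @export
surface_hydrophobicity <- function(x, scale = kyte_doolittle(), probe = 1.4,
                                   n_points = 960, radii = element_radii()) {
  sa <- if (inherits(x, "vhh_complex")) {
    sasa_shrake_rupley(x, probe, n_points, radii, chains = x$vhh_chain)
  } else {
    x
  }
  if (nrow(sa) == 0) return(0)
  sum(sa$sasa * scale[sa$residue])
}

#' Interface summary of a VHH-antigen complex
#'
#' Epitope and paratope residue sets at the contact threshold, per-segment
#' paratope counts, FR2 involvement, seven-class compositions of both
#' sides, and the acceptance flag of the minimum-epitope filter: complexes
#' whose epitope has fewer than `min_epitope` residues are flagged
#' `accepted = FALSE` (to be excluded from correlation input) to prevent
#' potential false interactions.
#'
#' @param m A `vhh_complex` with antigen chains.
#' @param threshold Contact distance in Angstrom (default 4).
#' @param min_epitope Minimum epitope residue count (default 6).
#' @param scheme Seven-class scheme, defaulting to [aa_classes()].
#' @return One-row tibble: `n_paratope`, `n_epitope`, `accepted`,
#'   `fr2_involved`, per-segment paratope counts
#'   (`paratope_FR1` ... `paratope_FR4`), and class fractions prefixed
#'   `paratope_class_` / `epitope_class_`.
#' @export
interface_summary <- function(m, threshold = 4, min_epitope = 6,
                              scheme = aa_classes()) {
  cc <- contact_residues(m, threshold, mode = "vhh_antigen")
  para <- dplyr::distinct(cc, .data$position_a, .data$insertion_a,
                          .data$residue_a, .data$region_a)
  epi <- dplyr::distinct(cc, .data$chain_b, .data$position_b,
                         .data$insertion_b, .data$residue_b)
  out <- tibble::tibble(
    n_paratope = nrow(para),
    n_epitope = nrow(epi),
    accepted = nrow(epi) >= min_epitope,
    fr2_involved = any(para$region_a == "FR2")
  )
  for (seg in REGION_LEVELS) {
    out[[paste0("paratope_", seg)]] <- sum(para$region_a == seg)
  }
  pcl <- if (nrow(para) > 0) {
    aa_class_fractions(paste(para$residue_a, collapse = ""), scheme)
  } else {
    aa_class_fractions("A", scheme)[0, ]
  }
  ecl <- if (nrow(epi) > 0) {
    aa_class_fractions(paste(epi$residue_b, collapse = ""), scheme)
  } else {
    aa_class_fractions("A", scheme)[0, ]
  }
  for (cl in names(pcl)) {
    out[[paste0("paratope_class_", cl)]] <-
      if (nrow(pcl) > 0) pcl[[cl]] else NA_real_
    out[[paste0("epitope_class_", cl)]] <-
      if (nrow(ecl) > 0) ecl[[cl]] else NA_real_
  }
  out
}

#' Secondary-structure usage of a region
#'
#' Fractions of the region's residues per DSSP code (H, G, I, E, T, S, C),
#' summing to 1 over the region. Requires secondary-structure labels on
#' the model; without them the fractions are `NA` (recorded, not fatal).
#'
#' @param m A `vhh_complex` with an `ss` table (see [vhh_complex()]).
#' @param region Region label as in [region_slice()].
#' @return One-row tibble with columns `ss_H` ... `ss_C`.
#' @export
ss_usage <- function(m, region = "CDR3") {
  codes <- c("H", "G", "I", "E", "T", "S", "C")
  out <- tibble::as_tibble(as.list(stats::setNames(
    rep(NA_real_, length(codes)), paste0("ss_", codes))))
  if (is.null(m$ss)) {
    warning("model has no secondary-structure labels", call. = FALSE)
    return(out)
  }
  res <- model_residues(m, m$vhh_chain)
  res <- res[!is.na(res$region) & res$region == region, ]
  if (nrow(res) == 0) return(out)
  key <- paste(res$chain, res$position, res$insertion)
  ss <- m$ss
  skey <- paste(ss$chain, ss$position, ss$insertion)
  lab <- ss$ss[match(key, skey)]
  lab <- lab[!is.na(lab)]
  if (length(lab) == 0) return(out)
  tab <- table(factor(lab, levels = codes))
  tibble::as_tibble(as.list(stats::setNames(
    as.numeric(tab) / length(lab), paste0("ss_", codes))))
}
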