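#' Net charge of a sequence at pH 7.4
#'
#' Sums per-residue formal charges: D and E -1, R and K +1, H +0.1, others 0.
#' `X` contributes 0 (with a warning); any other non-standard character is an
#' error. Charge is additive over concatenation.
#'
#' @param seq Character vector of amino-acid sequences (may be `""`).
#' @param scale Named numeric charge scale, defaulting to [charge_scale()].
#' @return Numeric vector of net charges; the empty sequence has charge 0.
#' @export
net_charge <- function(seq, scale = charge_scale()) {
  validate_aa(seq)
  vapply(split_residues(seq), function(ch) {
    if (length(ch) == 0) return(0)
    sum(scale[ch], na.rm = TRUE)
  }, numeric(1))
}

#' Mean Kyte-Doolittle hydropathy of a sequence
#'
#' Arithmetic mean of per-residue hydropathy indices over the sequence.
#' The mean over a concatenation is the length-weighted mean of the parts.
#'
#' @inheritParams net_charge
#' @param scale Named numeric hydropathy scale, defaulting to
#'   [kyte_doolittle()].
#' @return Numeric vector; `NA` for empty sequences (undefined mean).
#' @export
mean_hydropathy <- function(seq, scale = kyte_doolittle()) {
  validate_aa(seq)
  vapply(split_residues(seq), function(ch) {
    ch <- ch[ch != "X"]
    if (length(ch) == 0) return(NA_real_)
    mean(scale[ch])
  }, numeric(1))
}

#' Seven-class amino-acid composition of a sequence
#'
#' Fraction of residues in each of the seven biochemical classes
#' (aliphatic, aromatic, sulfur-containing, hydroxyl, basic, acidic, amine).
#' Fractions over a nonempty sequence sum to 1.
#'
#' @inheritParams net_charge
#' @param scheme Named character class map, defaulting to [aa_classes()].
#' @return A tibble with one row per input sequence and one column per class;
#'   all-`NA` rows for empty sequences.
#' @export
aa_class_fractions <- function(seq, scheme = aa_classes()) {
  validate_aa(seq)
  levels <- unique(unname(scheme))
  rows <- lapply(split_residues(seq), function(ch) {
    ch <- ch[ch != "X"]
    if (length(ch) == 0) {
      return(stats::setNames(rep(NA_real_, length(levels)), levels))
    }
    tab <- table(factor(scheme[ch], levels = levels))
    stats::setNames(as.numeric(tab) / length(ch), levels)
  })
  tibble::as_tibble(do.call(rbind, rows))
}

#' Per-member regional charge and hydropathy features
#'
#' One row per repertoire member with `cdr3_length` and, for each IMGT region
#' plus the pooled CDRs (`CDR` = CDR1+CDR2+CDR3) and the full sequence
#' (`VHH`), the net charge and mean hydropathy.
#'
#' @param x A `vhh_repertoire` (normally already filtered).
#' @param regions Region boundary table, defaulting to [imgt_regions()].
#' @return A tibble with columns `id`, `species`, `germline`, `cdr3_length`,
#'   and `charge_<REGION>` / `hydropathy_<REGION>` for the nine region labels.
#' @export
region_features <- function(x, regions = imgt_regions()) {
  out <- tibble::tibble(
    id = x$id, species = x$species, germline = x$germline,
    cdr3_length = x$cdr3_length
  )
  for (reg in c(REGION_LEVELS, "CDR", "VHH")) {
    sq <- region_slice(x, reg, regions)
    out[[paste0("charge_", reg)]] <- net_charge(sq)
    out[[paste0("hydropathy_", reg)]] <- suppressWarnings(mean_hydropathy(sq))
  }
  out
}
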