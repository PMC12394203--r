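#' Residue-level scales used throughout the package
#'
#' `charge_scale()` returns the per-residue formal charge at pH 7.4 used for
#' net-charge sums: D and E contribute -1, R and K +1, H +0.1, every other
#' standard residue 0. `kyte_doolittle()` returns the Kyte-Doolittle hydropathy
#' index for the 20 standard residues (C = 2.5, I = 4.5, R = -4.5, ...).
#' `aa_classes()` returns the default seven-class biochemical grouping used for
#' epitope/paratope composition: aliphatic, aromatic, sulfur-containing,
#' hydroxyl, basic, acidic, amine.
#'
#' All three return named numeric/character vectors keyed by one-letter residue
#' code, so they can be swapped for alternative scales by passing a vector of
#' the same shape to the functions that take a `scale` or `scheme` argument.
#'
#' @return `charge_scale()` and `kyte_doolittle()`: named numeric vectors over
#'   the 20 standard residues. `aa_classes()`: a named character vector mapping
#'   each residue to one of the seven class labels.
#' @examples
#' charge_scale()[c("D", "E", "R", "K", "H")]
#' kyte_doolittle()["C"]
#' table(aa_classes())
#' @name residue_scales
NULL

AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' @rdname residue_scales
#' @export
charge_scale <- function() {
  ch <- stats::setNames(rep(0, length(AA_STANDARD)), AA_STANDARD)
  ch[c("D", "E")] <- -1
  ch[c("R", "K")] <- 1
  ch["H"] <- 0.1
  ch
}

#' @rdname residue_scales
#' @export
kyte_doolittle <- function() {
  c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
    L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)
}

AA_CLASS_LEVELS <- c("aliphatic", "aromatic", "sulfur", "hydroxyl",
                     "basic", "acidic", "amine")

#' @rdname residue_scales
#' @export
aa_classes <- function() {
  cl <- c(A = "aliphatic", V = "aliphatic", L = "aliphatic", I = "aliphatic",
          G = "aliphatic", P = "aliphatic",
          F = "aromatic", W = "aromatic", Y = "aromatic",
          C = "sulfur", M = "sulfur",
          S = "hydroxyl", T = "hydroxyl",
          K = "basic", R = "basic", H = "basic",
          D = "acidic", E = "acidic",
          N = "amine", Q = "amine")
  cl[AA_STANDARD]
}

# Per-element van der Waals radii (Angstrom) for SASA; a fixed published table.
ELEMENT_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
                   P = 1.80, SE = 1.90)

#' Atomic radii used for solvent-accessible surface area
#'
#' Per-element van der Waals radii (Angstrom) used by
#' [sasa_shrake_rupley()]. Carbon 1.70, nitrogen 1.55, oxygen 1.52,
#' sulfur 1.80, hydrogen 1.20, phosphorus 1.80, selenium 1.90.
#'
#' @return Named numeric vector keyed by element symbol.
#' @export
element_radii <- function() ELEMENT_RADII

split_residues <- function(seq) {
  strsplit(seq, "", fixed = TRUE)
}

validate_aa <- function(seq, allow_x = TRUE, what = "sequence") {
  chars <- unique(unlist(split_residues(seq)))
  ok <- AA_STANDARD
  if (allow_x) ok <- c(ok, "X")
  bad <- setdiff(chars, ok)
  if (length(bad) > 0) {
    stop(sprintf("non-amino-acid character(s) in %s: %s",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (allow_x && any(chars == "X")) {
    warning("sequence contains 'X'; it contributes 0 to scale sums",
            call. = FALSE)
  }
  invisible(seq)
}
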