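#' Construct a VHH (or VHH-antigen) structure model
#'
#' The atom-level container used by the structural feature functions: a
#' tibble of atoms keyed by chain, IMGT residue number and insertion code,
#' plus the chain roles. Every residue of the VHH chain is labelled with its
#' IMGT region; antigen residues carry `NA` regions.
#'
#' @param atoms Tibble with columns `chain`, `position` (integer IMGT
#'   number for the VHH chain, author numbering for antigen chains),
#'   `insertion` (`""` when none), `residue` (one-letter), `atom_name`,
#'   `element`, `x`, `y`, `z` (Angstrom).
#' @param vhh_chain Chain id of the VHH.
#' @param antigen_chains Character vector of antigen chain ids (may be
#'   empty for an unbound VHH).
#' @param ss Optional per-residue secondary-structure tibble with columns
#'   `chain`, `position`, `insertion`, `ss` (DSSP codes H, G, I, E, T, S, C).
#' @param regions Region boundary table, defaulting to [imgt_regions()].
#' @return An object of class `vhh_complex`.
#' @export
vhh_complex <- function(atoms, vhh_chain, antigen_chains = character(),
                        ss = NULL, regions = imgt_regions()) {
  atoms <- tibble::as_tibble(atoms)
  need <- c("chain", "position", "insertion", "residue", "atom_name",
            "element", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0) {
    stop("atoms table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite atom coordinates", call. = FALSE)
  }
  if (vhh_chain %in% antigen_chains) {
    stop("VHH chain must be disjoint from antigen chains", call. = FALSE)
  }
  is_vhh <- atoms$chain == vhh_chain
  reg <- rep(NA_character_, nrow(atoms))
  for (k in seq_len(nrow(regions))) {
    in_reg <- is_vhh & atoms$position >= regions$start[k] &
      atoms$position <= regions$end[k]
    reg[in_reg] <- regions$region[k]
  }
  if (any(is_vhh & is.na(reg))) {
    bad <- unique(paste0(atoms$position[is_vhh & is.na(reg)],
                         atoms$insertion[is_vhh & is.na(reg)]))
    stop("VHH residue(s) outside IMGT 1..128, cannot assign region: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  atoms$region <- reg
  structure(list(atoms = atoms, vhh_chain = vhh_chain,
                 antigen_chains = antigen_chains, ss = ss),
            class = "vhh_complex")
}

#' @export
print.vhh_complex <- function(x, ...) {
  n_res <- nrow(unique(x$atoms[, c("chain", "position", "insertion")]))
  cat(sprintf("vhh_complex: %d atoms, %d residues; VHH chain %s%s\n",
              nrow(x$atoms), n_res, x$vhh_chain,
              if (length(x$antigen_chains) > 0)
                paste0(", antigen chain(s) ",
                       paste(x$antigen_chains, collapse = ",")) else ""))
  invisible(x)
}

#' Residue table of a model
#'
#' One row per residue in chain order with its region label.
#'
#' @param m A `vhh_complex`.
#' @param chain Optional chain id filter.
#' @return Tibble `chain`, `position`, `insertion`, `residue`, `region`.
#' @export
model_residues <- function(m, chain = NULL) {
  at <- m$atoms
  if (!is.null(chain)) at <- at[at$chain %in% chain, ]
  dplyr::distinct(at, .data$chain, .data$position, .data$insertion,
                  .data$residue, .data$region)
}

#' VHH amino-acid sequence of a model
#'
#' @param m A `vhh_complex`.
#' @return Single string of one-letter codes in chain order.
#' @export
model_sequence <- function(m) {
  res <- model_residues(m, m$vhh_chain)
  paste(res$residue, collapse = "")
}

#' Load a VHH-antigen complex from a PDB file
#'
#' Reads standard ATOM records via bio3d, excluding heteroatoms and waters,
#' resolving alternate locations to the highest occupancy and using the
#' first model of multi-model files. The chain map names the VHH chain and
#' the antigen chains and either asserts that the VHH chain is already
#' IMGT-renumbered or supplies an author-to-IMGT mapping table.
#'
#' @param path Path to a PDB file.
#' @param chainmap Either a list or a path to a JSON file with fields
#'   `vhh_chain` (string), `antigen_chains` (character vector, may be
#'   empty), and optionally `numbering_map`: a data frame with columns
#'   `author_position`, `author_insertion`, `imgt_position`,
#'   `imgt_insertion` applied to the VHH chain. Without a map the VHH chain
#'   is assumed IMGT-numbered; residues outside 1..128 raise an error
#'   naming them.
#' @param ss Optional path to a DSSP-format file providing secondary
#'   structure (see [read_dssp()]).
#' @return A `vhh_complex`.
#' @export
read_complex <- function(path, chainmap, ss = NULL) {
  if (is.character(chainmap)) {
    chainmap <- jsonlite::read_json(chainmap, simplifyVector = TRUE)
  }
  if (is.null(chainmap$vhh_chain)) stop("chainmap lacks vhh_chain",
                                        call. = FALSE)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT", "DOD")), ]
  chains <- c(chainmap$vhh_chain, chainmap$antigen_chains)
  missing_chain <- setdiff(chains, unique(at$chain))
  if (length(missing_chain) > 0) {
    stop("chain(s) not found in PDB: ",
         paste(missing_chain, collapse = ", "), call. = FALSE)
  }
  at <- at[at$chain %in% chains, ]
  # altloc: keep the highest-occupancy alternate of each atom
  alt_key <- paste(at$chain, at$resno, at$insert, at$elety)
  at <- at[order(-replace(at$o, is.na(at$o), 1)), ]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety)), ]
  at <- at[order(match(paste(at$chain, at$resno, at$insert, at$elety),
                       unique(alt_key))), ]
  ins <- ifelse(is.na(at$insert) | at$insert == " ", "", at$insert)
  res1 <- suppressWarnings(bio3d::aa321(at$resid))
  elem <- toupper(ifelse(is.na(at$elesy) | at$elesy == "",
                         substr(trimws(at$elety), 1, 1), at$elesy))
  atoms <- tibble::tibble(
    chain = at$chain, position = as.integer(at$resno), insertion = ins,
    residue = res1, atom_name = trimws(at$elety), element = elem,
    x = at$x, y = at$y, z = at$z
  )
  if (!is.null(chainmap$numbering_map)) {
    nm <- tibble::as_tibble(chainmap$numbering_map)
    isv <- atoms$chain == chainmap$vhh_chain
    key <- paste(atoms$position[isv], atoms$insertion[isv])
    mk <- paste(nm$author_position, nm$author_insertion)
    hit <- match(key, mk)
    if (anyNA(hit)) {
      stop("unmapped VHH residue(s): ",
           paste(unique(key[is.na(hit)]), collapse = ", "), call. = FALSE)
    }
    atoms$position[isv] <- as.integer(nm$imgt_position[hit])
    atoms$insertion[isv] <- as.character(nm$imgt_insertion[hit])
  }
  ss_tbl <- if (!is.null(ss)) read_dssp(ss) else NULL
  vhh_complex(atoms, chainmap$vhh_chain,
              as.character(chainmap$antigen_chains %||% character()),
              ss = ss_tbl)
}

#' Write a model to PDB format
#'
#' Emits standard ATOM records (via bio3d) in the order the atoms table is
#' stored; insertion codes are preserved.
#'
#' @param m A `vhh_complex`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_complex_pdb <- function(m, path) {
  at <- m$atoms
  xyz <- as.numeric(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(
    file = path, xyz = xyz,
    type = rep("ATOM", nrow(at)),
    resno = at$position,
    resid = bio3d::aa123(at$residue),
    insert = ifelse(at$insertion == "", "", at$insertion),
    chain = at$chain,
    elety = at$atom_name,
    eleno = seq_len(nrow(at)),
    elesy = at$element,
    o = rep(1, nrow(at)), b = rep(0, nrow(at))
  )
  invisible(path)
}

#' Read secondary-structure labels from a DSSP-format file
#'
#' Minimal fixed-column parser for classic DSSP output: data lines after the
#' `#  RESIDUE` header are read for residue number (columns 6-10), insertion
#' code (11), chain (12), amino acid (14) and the summary structure code
#' (17). Blank structure codes are loop/irregular and map to `C`; chain
#' breaks (`!` residues) are skipped.
#'
#' @param path Path to a DSSP file.
#' @return Tibble with columns `chain`, `position`, `insertion`, `ss`.
#' @export
read_dssp <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0) stop("not a DSSP-format file: ", path, call. = FALSE)
  body <- lines[(hdr[1] + 1):length(lines)]
  aa <- substr(body, 14, 14)
  body <- body[aa != "!" & nzchar(trimws(body))]
  ss <- substr(body, 17, 17)
  ss[ss == " "] <- "C"
  tibble::tibble(
    chain = substr(body, 12, 12),
    position = as.integer(substr(body, 6, 10)),
    insertion = trimws(substr(body, 11, 11)),
    ss = ss
  )
}

#' Write secondary-structure labels in DSSP format
#'
#' Emits the minimal classic-DSSP layout that [read_dssp()] ingests
#' (header line plus fixed-column residue records).
#'
#' @param ss Tibble with columns `chain`, `position`, `insertion`, `ss`,
#'   and optionally `residue` (one-letter code, defaults to `A`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dssp <- function(ss, path) {
  res <- if ("residue" %in% names(ss)) ss$residue else rep("A", nrow(ss))
  hdr <- c("==== Secondary structure assignment in DSSP dialect ====",
           "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC")
  lines <- sprintf("%5d%5d%1s%1s %1s  %1s",
                   seq_len(nrow(ss)), ss$position,
                   ifelse(ss$insertion == "", " ", ss$insertion),
                   ss$chain, res, ss$ss)
  writeLines(c(hdr, lines), path)
  invisible(path)
}
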