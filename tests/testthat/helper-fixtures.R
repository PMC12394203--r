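# Fixture builders and independent oracles used across the suite.

num_str <- function(position, insertion, residue) {
  paste(sprintf("%d:%s:%s", position, insertion, residue), collapse = ";")
}

# numbering string for a member that has only a CDR3 (other regions empty)
cdr3_only_numbering <- function(cdr3) {
  cp <- imgt_cdr3_positions(nchar(cdr3))
  num_str(cp$position, cp$insertion, strsplit(cdr3, "")[[1]])
}

# write a repertoire TSV and read it back as a vhh_repertoire
make_repertoire <- function(ids, cdr3, counts, germline = NULL,
                            species = "alpaca") {
  tbl <- data.frame(
    id = ids, sequence = cdr3,
    numbering = vapply(cdr3, cdr3_only_numbering, character(1)),
    count = counts, stringsAsFactors = FALSE
  )
  if (!is.null(germline)) tbl$germline <- germline
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  readr::write_tsv(tbl, path, progress = FALSE)
  read_repertoire(path, species)
}

random_cdr3 <- function(len) {
  paste(sample(c("G", "S", "A", "Y", "D", "R", "T", "V"), len,
               replace = TRUE), collapse = "")
}

# ---- structural fixtures --------------------------------------------------

atom_row <- function(chain, position, insertion, residue, x, y, z,
                     atom_name = "CA", element = "C") {
  tibble::tibble(chain = chain, position = as.integer(position),
                 insertion = insertion, residue = residue,
                 atom_name = atom_name, element = element,
                 x = x, y = y, z = z)
}

# minimal model: residue 42 at the origin plus a CDR3 whose residues sit at
# given centroid positions (one atom each), plus filler to anchor regions
simple_model <- function(cdr3_xyz, antigen_xyz = NULL) {
  # residue 42 at the origin; a remote FR2 spacer at 50 keeps position 42
  # and the first CDR3 residue non-adjacent in chain order
  rows <- list(atom_row("A", 42, "", "W", 0, 0, 0),
               atom_row("A", 50, "", "G", 50, 50, 50))
  cp <- imgt_cdr3_positions(nrow(cdr3_xyz))
  for (k in seq_len(nrow(cdr3_xyz))) {
    rows[[length(rows) + 1]] <- atom_row(
      "A", cp$position[k], cp$insertion[k], "G",
      cdr3_xyz[k, 1], cdr3_xyz[k, 2], cdr3_xyz[k, 3])
  }
  ag <- character(0)
  if (!is.null(antigen_xyz)) {
    for (k in seq_len(nrow(antigen_xyz))) {
      rows[[length(rows) + 1]] <- atom_row(
        "B", k, "", "A",
        antigen_xyz[k, 1], antigen_xyz[k, 2], antigen_xyz[k, 3])
    }
    ag <- "B"
  }
  vhh_complex(dplyr::bind_rows(rows), "A", ag)
}

# random multi-atom model over a handful of regions
random_model <- function(n_res = 30, n_antigen = 0, seed = 1,
                         spread = 12) {
  set.seed(seed)
  positions <- sort(sample(c(1:26, 39:55, 66:104, 105:117, 118:128), n_res))
  rows <- lapply(seq_along(positions), function(k) {
    cen <- stats::runif(3, 0, spread)
    n_at <- sample(2:3, 1)
    atom_row("A", positions[k], "", sample(c("A", "G", "Y", "D"), 1),
             cen[1] + stats::rnorm(n_at, sd = 0.8),
             cen[2] + stats::rnorm(n_at, sd = 0.8),
             cen[3] + stats::rnorm(n_at, sd = 0.8),
             atom_name = c("CA", "CB", "O")[seq_len(n_at)],
             element = sample(c("C", "N", "O"), n_at, replace = TRUE))
  })
  ag <- character(0)
  if (n_antigen > 0) {
    for (k in seq_len(n_antigen)) {
      cen <- stats::runif(3, 0, spread)
      rows[[length(rows) + 1]] <- atom_row(
        "B", k, "", "A", cen[1] + stats::rnorm(2, sd = 0.8),
        cen[2] + stats::rnorm(2, sd = 0.8), cen[3] + stats::rnorm(2, sd = 0.8),
        atom_name = c("CA", "CB"), element = "C")
    }
    ag <- "B"
  }
  vhh_complex(dplyr::bind_rows(rows), "A", ag)
}

# ---- independent oracles --------------------------------------------------

# naive all-pairs residue contact scan (triple loop, no vectorized reuse)
brute_contacts <- function(m, threshold = 4, mode = "vhh_antigen") {
  at <- m$atoms
  res <- model_residues(m)
  keys <- paste(res$chain, res$position, res$insertion)
  out <- list()
  for (i in seq_len(nrow(res))) {
    for (j in seq_len(nrow(res))) {
      if (mode == "vhh_antigen") {
        if (!(res$chain[i] == m$vhh_chain &&
              res$chain[j] %in% m$antigen_chains)) next
      } else {
        if (!(res$chain[i] == m$vhh_chain && res$chain[j] == m$vhh_chain))
          next
        if (j <= i + 1) next  # self and sequence-adjacent excluded
      }
      ai <- at[paste(at$chain, at$position, at$insertion) == keys[i], ]
      aj <- at[paste(at$chain, at$position, at$insertion) == keys[j], ]
      best <- Inf
      for (p in seq_len(nrow(ai))) {
        for (q in seq_len(nrow(aj))) {
          d <- sqrt((ai$x[p] - aj$x[q])^2 + (ai$y[p] - aj$y[q])^2 +
                      (ai$z[p] - aj$z[q])^2)
          if (d < best) best <- d
        }
      }
      if (best <= threshold) {
        out[[length(out) + 1]] <- data.frame(key_a = keys[i],
                                             key_b = keys[j],
                                             min_dist = best)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(key_a = character(), key_b = character(),
                      min_dist = numeric()))
  }
  do.call(rbind, out)
}

# independent FR2_CDR3_Dis arithmetic (own grouping and centroid code)
brute_fr2_dis <- function(m) {
  at <- m$atoms[m$atoms$chain == m$vhh_chain & m$atoms$element != "H", ]
  cen_of <- function(sub) c(mean(sub$x), mean(sub$y), mean(sub$z))
  p42 <- cen_of(at[at$position == 42, ])
  res <- model_residues(m, m$vhh_chain)
  cdr3 <- res[res$region == "CDR3" & !is.na(res$region), ]
  cdr3 <- cdr3[3:(nrow(cdr3) - 2), ]
  dists <- vapply(seq_len(nrow(cdr3)), function(k) {
    sub <- at[at$position == cdr3$position[k] &
                at$insertion == cdr3$insertion[k], ]
    sqrt(sum((cen_of(sub) - p42)^2))
  }, numeric(1))
  min(dists)
}

# analytic SASA of two overlapping solvent-expanded spheres
two_sphere_sasa <- function(r1, r2, d, probe = 1.4) {
  R1 <- r1 + probe; R2 <- r2 + probe
  if (d >= R1 + R2) return(c(4 * pi * R1^2, 4 * pi * R2^2))
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  c(4 * pi * R1^2 - 2 * pi * R1 * h1,
    4 * pi * R2^2 - 2 * pi * R2 * h2)
}

# exact Mann-Whitney two-sided p by enumeration of all group assignments
brute_mwu <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  u_of <- function(idx) {
    ra <- rank(pooled)[idx]
    sum(ra) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  all_u <- apply(utils::combn(n1 + n2, n1), 2, u_of)
  p_le <- mean(all_u <= u_obs)
  p_ge <- mean(all_u >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

rigid_transform <- function(atoms, seed = 99) {
  set.seed(seed)
  th <- stats::runif(3, 0, 2 * pi)
  rx <- matrix(c(1, 0, 0, 0, cos(th[1]), -sin(th[1]),
                 0, sin(th[1]), cos(th[1])), 3, byrow = TRUE)
  rz <- matrix(c(cos(th[2]), -sin(th[2]), 0, sin(th[2]), cos(th[2]), 0,
                 0, 0, 1), 3, byrow = TRUE)
  rot <- rz %*% rx
  shift <- stats::runif(3, -20, 20)
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(rot)
  atoms$x <- xyz[, 1] + shift[1]
  atoms$y <- xyz[, 2] + shift[2]
  atoms$z <- xyz[, 3] + shift[3]
  atoms
}

# a single neutral germline: no length preference, no hallmark switches
default_germline_neutral <- function() {
  tibble::tibble(
    name = "neutral", weight = 1, length_shift = 0,
    res35 = "S", res36 = "A", res37 = "A", res39 = "Q", res42 = "Y",
    res49 = "A", res52 = "L", res55 = "S", res62 = "S", p_n105 = 0.3
  )
}
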