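# Pseudo-fold scaffold: framework strands on a cylinder with CDR loops at
# the top face. Coordinates are fixtures for geometry code, not physical
# protein models; each residue carries one backbone-like centroid atom plus
# two side-chain pseudo-atoms.

scaffold_strands <- function() {
  # position range, angle (degrees), direction (+1 up, -1 down)
  list(
    list(pos = 1:13,    theta = 0,   dir = -1),
    list(pos = 14:26,   theta = 40,  dir = +1),
    list(pos = 39:47,   theta = 80,  dir = -1),  # FR2 strand holding IMGT 42
    list(pos = 48:55,   theta = 115, dir = +1),
    list(pos = 66:75,   theta = 150, dir = -1),
    list(pos = 76:85,   theta = 195, dir = +1),
    list(pos = 86:95,   theta = 240, dir = -1),
    list(pos = 96:104,  theta = 330, dir = +1),  # ends at the CDR3 anchor
    list(pos = 118:128, theta = 305, dir = -1)
  )
}

scaffold_coords <- function(cdr1_len = 8, cdr2_len = 8, radius = 7.5,
                            height = 24) {
  rows <- list()
  for (s in scaffold_strands()) {
    k <- length(s$pos)
    z <- if (s$dir > 0) seq(0, height, length.out = k) else
      seq(height, 0, length.out = k)
    th <- s$theta * pi / 180
    rows[[length(rows) + 1]] <- data.frame(
      position = s$pos, insertion = "",
      x = radius * cos(th), y = radius * sin(th), z = z)
  }
  arc <- function(positions, th1, th2, r = radius + 1.5, zc = height + 2.5) {
    k <- length(positions)
    th <- seq(th1, th2, length.out = k) * pi / 180
    data.frame(position = positions, insertion = "",
               x = r * cos(th), y = r * sin(th),
               z = zc + 1.5 * sin(seq(0, pi, length.out = k)))
  }
  rows[[length(rows) + 1]] <- arc(imgt_loop_positions(27, 38, cdr1_len),
                                  40, 80)
  rows[[length(rows) + 1]] <- arc(imgt_loop_positions(56, 65, cdr2_len),
                                  115, 150)
  out <- do.call(rbind, rows)
  out[order(out$position), ]
}

# piecewise-linear path through waypoints resampled at k points
resample_path <- function(waypoints, k) {
  seglen <- sqrt(rowSums(diff(waypoints)^2))
  cum <- c(0, cumsum(seglen))
  t <- seq(0, cum[length(cum)], length.out = k + 2)[2:(k + 1)]
  sapply(1:3, function(j) stats::approx(cum, waypoints[, j], xout = t)$y)
}

#' Recipe for a synthetic VHH-antigen structure set
#'
#' Defines a set of pseudo-structures with the geometry the structural
#' analyses assume: a fixed framework scaffold with labelled IMGT positions
#' including 42, a CDR3 loop that is either extended (projecting away from
#' the position-42 anchor) or bent (routed past CDR2 toward position 42,
#' yielding a small FR2-CDR3 distance), longer loops biased toward bent, an
#' antigen blob docked onto a recipe-controlled paratope segment mix (CDR3
#' contacts growing with length, FR2 involvement shrinking), and
#' conformation-specific secondary-structure label emission.
#'
#' @param n Number of complexes (default 200).
#' @param bent_fraction Target marginal fraction of bent CDR3 conformations
#'   (default 0.5); 1 or 0 force a single conformation.
#' @param length_mean,length_std CDR3 length distribution (discretized
#'   normal truncated at 5; defaults 15.7 / 4.6).
#' @param dis_bent_mean,dis_bent_sd FR2-CDR3 distance component for bent
#'   loops (default 7 and 0.8 Angstrom).
#' @param dis_ext_mean,dis_ext_sd Component for extended loops (default 15
#'   and 1.2 Angstrom).
#' @param length_link_scale Logistic scale (in residues) linking length to
#'   the bent conformation (default 2.5).
#' @param fr2_paratope_mid,fr2_paratope_scale Logistic midpoint/scale of
#'   the probability that FR2 joins the paratope, decreasing with CDR3
#'   length (defaults 16 and 2.5).
#' @param min_epitope Minimum antigen residues placed in contact
#'   (default 8, comfortably above the epitope-size filter).
#' @param seed Integer RNG seed.
#' @return A list of class `structure_recipe`.
#' @export
structure_recipe <- function(n = 200, bent_fraction = 0.5,
                             length_mean = 15.7, length_std = 4.6,
                             dis_bent_mean = 7, dis_bent_sd = 0.8,
                             dis_ext_mean = 15, dis_ext_sd = 1.2,
                             length_link_scale = 2.5,
                             fr2_paratope_mid = 16, fr2_paratope_scale = 2.5,
                             min_epitope = 8, seed = 7L) {
  stopifnot(bent_fraction >= 0, bent_fraction <= 1, n >= 1)
  structure(list(
    n = n, bent_fraction = bent_fraction, length_mean = length_mean,
    length_std = length_std, dis_bent_mean = dis_bent_mean,
    dis_bent_sd = dis_bent_sd, dis_ext_mean = dis_ext_mean,
    dis_ext_sd = dis_ext_sd, length_link_scale = length_link_scale,
    fr2_paratope_mid = fr2_paratope_mid,
    fr2_paratope_scale = fr2_paratope_scale,
    min_epitope = min_epitope, seed = as.integer(seed)
  ), class = "structure_recipe")
}

SS_EMISSION <- list(
  bent = c(H = 0.00, G = 0.15, I = 0.00, E = 0.05, T = 0.15,
           S = 0.25, C = 0.40),
  extended = c(H = 0.00, G = 0.02, I = 0.00, E = 0.35, T = 0.25,
               S = 0.13, C = 0.25)
)

residue_atoms <- function(position, insertion, residue, center, jitter = 1.6) {
  offs1 <- stats::rnorm(3); offs1 <- offs1 / sqrt(sum(offs1^2)) * jitter
  offs2 <- stats::rnorm(3); offs2 <- offs2 / sqrt(sum(offs2^2)) * (jitter - 0.2)
  data.frame(
    position = position, insertion = insertion, residue = residue,
    atom_name = c("CA", "CB", "O"), element = c("C", "C", "O"),
    x = center[1] + c(0, offs1[1], offs2[1]),
    y = center[2] + c(0, offs1[2], offs2[2]),
    z = center[3] + c(0, offs1[3], offs2[3]),
    stringsAsFactors = FALSE
  )
}

build_one_structure <- function(recipe, L, bent, target_dis, scaffold,
                                fr2_involved) {
  sc <- scaffold
  p42 <- as.numeric(sc[sc$position == 42, c("x", "y", "z")])

  anchor_s <- as.numeric(sc[sc$position == 104, c("x", "y", "z")])
  anchor_e <- as.numeric(sc[sc$position == 118, c("x", "y", "z")])
  cdr2_rows <- sc[sc$position >= 56 & sc$position <= 65, ]
  cdr2_cen <- c(mean(cdr2_rows$x), mean(cdr2_rows$y), mean(cdr2_rows$z))

  if (bent) {
    # route the loop past CDR2 and down to the position-42 anchor
    w_cdr2 <- cdr2_cen + c(cdr2_cen[1], cdr2_cen[2], 0) /
      sqrt(sum(cdr2_cen[1:2]^2)) * 3.0
    u_out <- c(p42[1], p42[2], 1.0)
    u_out <- u_out / sqrt(sum(u_out^2))
    w_42 <- p42 + u_out * target_dis
    r54 <- as.numeric(sc[sc$position == 54, c("x", "y", "z")])
    u54 <- c(r54[1], r54[2], 2.0)
    u54 <- u54 / sqrt(sum(u54^2))
    w_fr2 <- r54 + u54 * 2.8
    way <- rbind(anchor_s + c(0, 0, 3), w_cdr2, w_fr2, w_42,
                 anchor_e + c(0, 0, 3))
  } else {
    apex0 <- c(4 * cos(318 * pi / 180), 4 * sin(318 * pi / 180),
               26 + 0.6 * L)
    u <- apex0 - p42
    u <- u / sqrt(sum(u^2))
    w_apex <- p42 + u * target_dis
    way <- rbind(anchor_s + c(0, 0, 2), w_apex, anchor_e + c(0, 0, 2))
  }
  path <- resample_path(way, L)
  path <- path + matrix(stats::rnorm(3 * L, sd = 0.3), ncol = 3)

  # fine-tune: rigidly translate the loop so the trimmed-residue minimum
  # centroid distance to position 42 equals the drawn target
  if (L >= 5) {
    trim <- 3:(L - 2)
    for (it in 1:3) {
      d <- sqrt(rowSums(sweep(path[trim, , drop = FALSE], 2, p42)^2))
      j <- trim[which.min(d)]
      cur <- min(d)
      u <- (path[j, ] - p42) / cur
      path <- sweep(path, 2, u * (target_dis - cur), "+")
    }
  }

  cdr3_positions <- imgt_cdr3_positions(L)
  bg <- cdr3_background()
  cdr3_res <- sample(AA_STANDARD, L, replace = TRUE, prob = bg)

  scaffold_seq <- c(
    strsplit(paste0(FR1_TEMPLATE, CDR1_TEMPLATE, FR2_TEMPLATE,
                    CDR2_TEMPLATE, FR3_TEMPLATE, FR4_TEMPLATE), "")[[1]]
  )
  sc_sorted <- sc
  sc_sorted$residue <- scaffold_seq[rank(sc_sorted$position,
                                         ties.method = "first")]

  # build atoms in chain order: framework up to 104, CDR3, then FR4
  atoms <- list()
  pre <- sc_sorted[sc_sorted$position <= 104, ]
  post <- sc_sorted[sc_sorted$position >= 118, ]
  for (k in seq_len(nrow(pre))) {
    atoms[[length(atoms) + 1]] <- residue_atoms(
      pre$position[k], "", pre$residue[k],
      as.numeric(pre[k, c("x", "y", "z")]))
  }
  for (k in seq_len(L)) {
    atoms[[length(atoms) + 1]] <- residue_atoms(
      cdr3_positions$position[k], cdr3_positions$insertion[k],
      cdr3_res[k], path[k, ])
  }
  for (k in seq_len(nrow(post))) {
    atoms[[length(atoms) + 1]] <- residue_atoms(
      post$position[k], "", post$residue[k],
      as.numeric(post[k, c("x", "y", "z")]))
  }
  vhh_atoms <- do.call(rbind, atoms)
  vhh_atoms$chain <- "A"

  # ---- antigen: one residue docked onto each chosen paratope residue ----
  res_tbl <- unique(vhh_atoms[, c("position", "insertion", "residue")])
  centroid_of <- function(pos, ins = "") {
    a <- vhh_atoms[vhh_atoms$position == pos & vhh_atoms$insertion == ins, ]
    c(mean(a$x), mean(a$y), mean(a$z))
  }
  k3 <- min(max(round(0.45 * (L - 4)), 2), 10)
  mid <- ceiling(L / 2)
  cdr3_pick <- unique(pmin(pmax(mid + seq_len(k3) - ceiling(k3 / 2), 3),
                           L - 2))
  targets <- lapply(cdr3_pick, function(k) {
    list(pos = cdr3_positions$position[k], ins = cdr3_positions$insertion[k],
         seg = "CDR3")
  })
  cdr1_top <- imgt_loop_positions(27, 38, 8)
  if (stats::runif(1) < 0.7) {
    for (p in utils::tail(cdr1_top, 2)) {
      targets[[length(targets) + 1]] <- list(pos = p, ins = "", seg = "CDR1")
    }
  }
  if (fr2_involved) {
    for (p in c(54, 55)) {
      targets[[length(targets) + 1]] <- list(pos = p, ins = "", seg = "FR2")
    }
  }
  if (stats::runif(1) < 0.3) {
    targets[[length(targets) + 1]] <- list(pos = 62, ins = "", seg = "CDR2")
  }
  topup <- c(103, 104, 118, 119, 102, 101)
  ti <- 1
  while (length(targets) < recipe$min_epitope && ti <= length(topup)) {
    targets[[length(targets) + 1]] <- list(pos = topup[ti], ins = "",
                                           seg = "other")
    ti <- ti + 1
  }

  ag_atoms <- list()
  ag_bg <- cdr3_background()
  for (k in seq_along(targets)) {
    tg <- targets[[k]]
    cen <- centroid_of(tg$pos, tg$ins)
    out_dir <- c(cen[1], cen[2], max(cen[3] - 12, 1))
    out_dir <- out_dir / sqrt(sum(out_dir^2))
    ag_cen <- cen + out_dir * 3.1
    ag_atoms[[k]] <- residue_atoms(k, "",
                                   sample(AA_STANDARD, 1, prob = ag_bg),
                                   ag_cen, jitter = 0.9)
  }
  n_fill <- max(0, 14 - length(targets))
  if (n_fill > 0) {
    base <- colMeans(do.call(rbind, lapply(ag_atoms, function(a) {
      c(mean(a$x), mean(a$y), mean(a$z))
    })))
    axis_dir <- c(base[1], base[2], max(base[3] - 12, 1))
    axis_dir <- axis_dir / sqrt(sum(axis_dir^2))
    for (k in seq_len(n_fill)) {
      cen <- base + axis_dir * (5 + 2.2 * k) +
        stats::rnorm(3, sd = 0.8)
      ag_atoms[[length(ag_atoms) + 1]] <- residue_atoms(
        length(targets) + k, "", sample(AA_STANDARD, 1, prob = ag_bg),
        cen, jitter = 0.9)
    }
  }
  ag <- do.call(rbind, ag_atoms)
  ag$chain <- "B"

  atoms_all <- rbind(vhh_atoms, ag)

  # secondary-structure labels: strands E, loops per conformation emission
  emis <- if (bent) SS_EMISSION$bent else SS_EMISSION$extended
  ss_codes <- names(emis)
  res_v <- unique(vhh_atoms[, c("position", "insertion")])
  in_cdr3 <- res_v$position >= 105 & res_v$position <= 117
  ss_lab <- character(nrow(res_v))
  ss_lab[!in_cdr3] <- ifelse(
    res_v$position[!in_cdr3] %in% unlist(lapply(scaffold_strands(),
                                                `[[`, "pos")),
    "E", "C")
  ss_lab[in_cdr3] <- sample(ss_codes, sum(in_cdr3), replace = TRUE,
                            prob = emis)
  ss <- tibble::tibble(chain = "A", position = res_v$position,
                       insertion = res_v$insertion, ss = ss_lab)

  vhh_complex(atoms_all, vhh_chain = "A", antigen_chains = "B", ss = ss)
}

#' Generate a synthetic set of VHH-antigen pseudo-structures
#'
#' Draws `recipe$n` complexes under a [structure_recipe()]. CDR3 lengths
#' come from a truncated discretized normal; the bent conformation is
#' assigned with a probability increasing in length (calibrated so the
#' marginal bent fraction matches the recipe); the FR2-CDR3 distance of
#' each structure is drawn from the conformation's component and realized
#' exactly in the coordinates; the antigen is docked so CDR3 contact counts
#' grow with length while FR2 involvement shrinks. Deterministic given the
#' recipe seed.
#'
#' @param recipe A [structure_recipe()].
#' @param dir Optional directory; when given, writes one PDB and one
#'   DSSP-format file per structure, a shared `chainmap.json`, and
#'   `ground_truth.json`.
#' @return A list with `models` (list of `vhh_complex`) and `truth`
#'   (tibble: `id`, `cdr3_length`, `conformation`, `target_dis`,
#'   `fr2_involved`, `n_cdr3_paratope_planted`).
#' @export
simulate_structures <- function(recipe, dir = NULL) {
  stopifnot(inherits(recipe, "structure_recipe"))
  with_seed(recipe$seed, {
    n <- recipe$n
    len <- integer(n)
    todo <- rep(TRUE, n)
    while (any(todo)) {
      raw <- stats::rnorm(sum(todo), recipe$length_mean, recipe$length_std)
      len[todo] <- as.integer(round(raw))
      todo[todo] <- len[todo] < 5
    }
    if (recipe$bent_fraction >= 1) {
      bent <- rep(TRUE, n)
    } else if (recipe$bent_fraction <= 0) {
      bent <- rep(FALSE, n)
    } else {
      q <- stats::quantile(len, 1 - recipe$bent_fraction)
      p_bent <- stats::plogis((len - q) / recipe$length_link_scale)
      bent <- stats::runif(n) < p_bent
    }
    target_dis <- ifelse(
      bent,
      stats::rnorm(n, recipe$dis_bent_mean, recipe$dis_bent_sd) -
        0.08 * (len - recipe$length_mean),
      stats::rnorm(n, recipe$dis_ext_mean, recipe$dis_ext_sd) -
        0.08 * (len - recipe$length_mean))
    target_dis <- pmax(target_dis, 3.5)
    p_fr2 <- stats::plogis((recipe$fr2_paratope_mid - len) /
                             recipe$fr2_paratope_scale)
    fr2_involved <- stats::runif(n) < p_fr2

    scaffold <- scaffold_coords()
    models <- vector("list", n)
    planted_k3 <- integer(n)
    for (i in seq_len(n)) {
      models[[i]] <- build_one_structure(recipe, len[i], bent[i],
                                         target_dis[i], scaffold,
                                         fr2_involved[i])
      planted_k3[i] <- min(max(round(0.45 * (len[i] - 4)), 2), 10)
    }
    ids <- sprintf("synth%03d", seq_len(n))
    truth <- tibble::tibble(
      id = ids, cdr3_length = len,
      conformation = ifelse(bent, "bent", "extended"),
      target_dis = target_dis, fr2_involved = fr2_involved,
      n_cdr3_paratope_planted = planted_k3
    )
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      for (i in seq_len(n)) {
        write_complex_pdb(models[[i]], file.path(dir, paste0(ids[i], ".pdb")))
        ssr <- models[[i]]$ss
        res <- model_residues(models[[i]], "A")
        ssr$residue <- res$residue[match(
          paste(ssr$position, ssr$insertion),
          paste(res$position, res$insertion))]
        write_dssp(ssr, file.path(dir, paste0(ids[i], ".dssp")))
      }
      jsonlite::write_json(
        list(vhh_chain = "A", antigen_chains = "B"),
        file.path(dir, "chainmap.json"), auto_unbox = TRUE)
      jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                           digits = NA)
    }
    list(models = models, truth = truth)
  })
}
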