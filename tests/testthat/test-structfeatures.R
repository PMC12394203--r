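test_that("contacts respect the 4 A threshold exactly", {
  m <- simple_model(cbind(c(3.9, 10, 20, 30, 40), 0, 0))
  cc <- contact_residues(m, mode = "intra_vhh")
  # residue 42 is 3.9 A from the first CDR3 residue, nothing else in range
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$min_dist, 3.9)

  m2 <- simple_model(cbind(c(4.1, 10, 20, 30, 40), 0, 0))
  cc2 <- contact_residues(m2, mode = "intra_vhh")
  expect_equal(nrow(cc2), 0L)

  # a model without CDR3 has an all-zero interaction profile
  m3 <- m
  m3$atoms <- m3$atoms[is.na(m3$atoms$region) | m3$atoms$region != "CDR3", ]
  expect_true(all(segment_interaction_profile(m3)$n_pairs == 0L))
})

test_that("contact scan equals the brute-force all-pairs oracle", {
  for (seed in 1:25) {
    m <- random_model(n_res = 20, n_antigen = 6, seed = seed, spread = 14)
    for (mode in c("vhh_antigen", "intra_vhh")) {
      got <- contact_residues(m, mode = mode)
      want <- brute_contacts(m, mode = mode)
      key_got <- sort(paste(got$chain_a, got$position_a, got$insertion_a,
                            got$chain_b, got$position_b, got$insertion_b))
      key_want <- sort(paste(want$key_a, want$key_b))
      expect_equal(key_got, key_want)
      expect_equal(sort(got$min_dist), sort(want$min_dist),
                   tolerance = 1e-12)
    }
  }
})

test_that("FR2_CDR3_Dis is the minimum trimmed-centroid distance", {
  # trimmed centroids at 5, 7, 9 A; first/last two excluded
  m <- simple_model(cbind(c(100, 100, 5, 7, 9, 100, 100), 0, 0))
  expect_equal(fr2_cdr3_dis(m), 5)

  # exactly 5 residues: only the middle one counts
  m5 <- simple_model(cbind(c(1, 1, 8, 1, 1), 0, 0))
  expect_equal(fr2_cdr3_dis(m5), 8)

  # shorter than 5: undefined with a warning
  m4 <- simple_model(cbind(c(1, 2, 3, 4), 0, 0))
  expect_warning(v <- fr2_cdr3_dis(m4), "undefined")
  expect_true(is.na(v))

  # missing position 42
  m_no42 <- simple_model(cbind(1:5, 0, 0))
  m_no42$atoms <- m_no42$atoms[m_no42$atoms$position != 42, ]
  expect_error(fr2_cdr3_dis(m_no42), "position 42")

  # random fixtures: equals the independent arithmetic oracle to 1e-9
  for (seed in 1:10) {
    m <- random_model(n_res = 25, seed = seed)
    if (sum(model_residues(m, "A")$region == "CDR3", na.rm = TRUE) < 5) next
    if (!42 %in% model_residues(m, "A")$position) next
    expect_equal(fr2_cdr3_dis(m), brute_fr2_dis(m), tolerance = 1e-9)
  }
})

test_that("FR2_CDR3_Dis is rigid-invariant and monotone under extension", {
  m <- simple_model(cbind(c(20, 15, 12, 9, 11, 14, 21), 0, 0))
  d0 <- fr2_cdr3_dis(m)
  mt <- m
  mt$atoms <- rigid_transform(mt$atoms)
  expect_equal(fr2_cdr3_dis(mt), d0, tolerance = 1e-9)

  # appending a closer residue to the trimmed set can only decrease the min
  m_more <- simple_model(cbind(c(20, 15, 12, 9, 6, 11, 14, 21), 0, 0))
  expect_lte(fr2_cdr3_dis(m_more), d0)
})

test_that("Shrake-Rupley SASA matches closed forms for spheres", {
  one <- atom_row("A", 1, "", "G", 0, 0, 0)
  s1 <- sasa_shrake_rupley(one)
  exact <- 4 * pi * (1.70 + 1.4)^2
  expect_lt(abs(s1$sasa - exact) / exact, 0.005)

  # two atoms far apart: no occlusion
  two_far <- dplyr::bind_rows(atom_row("A", 1, "", "G", 0, 0, 0),
                              atom_row("A", 2, "", "G", 100, 0, 0))
  s2 <- sasa_shrake_rupley(two_far)
  expect_equal(s2$sasa, rep(s1$sasa, 2), tolerance = 1e-9)

  # overlapping pair at stated radii/separation vs the analytic
  # spherical-cap areas, within 2%
  for (d in c(1.5, 2.5, 3.5)) {
    pair <- dplyr::bind_rows(
      atom_row("A", 1, "", "G", 0, 0, 0, element = "C"),
      atom_row("A", 2, "", "G", d, 0, 0, element = "O"))
    got <- sasa_shrake_rupley(pair)$sasa
    want <- two_sphere_sasa(1.70, 1.52, d)
    expect_lt(max(abs(got - want) / want), 0.02)
  }

  expect_error(sasa_shrake_rupley(atom_row("A", 1, "", "G", 0, 0, 0,
                                           element = "ZZ")),
               "unknown element")
})

test_that("SASA is invariant under rigid transforms", {
  # the fixed point grid does not rotate with the molecule, so agreement
  # tightens with the point count: total SASA to 0.1% at a dense grid,
  # per-residue to ~1% there and ~3% at the default grid
  m <- random_model(n_res = 15, seed = 4)
  mt <- m
  mt$atoms <- rigid_transform(mt$atoms, seed = 123)

  s0d <- sasa_shrake_rupley(m)
  s1d <- sasa_shrake_rupley(mt)
  expect_lt(max(abs(s1d$sasa - s0d$sasa) / pmax(s0d$sasa, 1)), 0.03)

  s0 <- sasa_shrake_rupley(m, n_points = 10000)
  s1 <- sasa_shrake_rupley(mt, n_points = 10000)
  expect_lt(abs(sum(s1$sasa) - sum(s0$sasa)) / sum(s0$sasa), 0.001)
  expect_lt(max(abs(s1$sasa - s0$sasa) / pmax(s0$sasa, 1)), 0.01)
})

test_that("buried surface area bookkeeping is consistent", {
  # far-apart chains: no interface
  far <- simple_model(cbind(c(6, 7, 8, 9, 10), 0, 0),
                      antigen_xyz = cbind(100 + 1:6 * 8, 0, 0))
  b_far <- buried_surface_area(far)
  expect_lt(abs(b_far$interface_bsa), 1)

  # docked pair: the two sides sum to the interface total within 1%
  set.seed(2)
  dock <- simple_model(cbind(c(6, 8, 10, 12, 14), 0, 0),
                       antigen_xyz = cbind(c(6, 8, 10, 12, 14, 10), 3,
                                           c(0, 0, 0, 0, 0, 3)))
  b <- buried_surface_area(dock)
  expect_gt(b$interface_bsa, 10)
  expect_lt(abs(b$interface_bsa - (b$paratope_bsa + b$epitope_bsa)) /
              b$interface_bsa, 0.01)

  # removing a residue far from the interface barely moves the total
  far_res <- simple_model(cbind(c(6, 8, 10, 12, 80), 0, 0),
                          antigen_xyz = cbind(c(6, 8, 10, 12, 10, 8), 3,
                                              c(0, 0, 0, 0, 3, 3)))
  b_full <- buried_surface_area(far_res)
  trimmed <- far_res
  trimmed$atoms <- trimmed$atoms[!(trimmed$atoms$chain == "A" &
                                     trimmed$atoms$x > 70), ]
  b_trim <- buried_surface_area(trimmed)
  expect_lt(abs(b_full$interface_bsa - b_trim$interface_bsa), 1)
})

test_that("surface hydrophobicity is the SASA-weighted hydropathy sum", {
  gly <- simple_model(cbind(c(6, 9, 12, 15, 18), 0, 0))
  gly$atoms$residue <- "G"
  sa <- sasa_shrake_rupley(gly, chains = "A")
  expect_equal(surface_hydrophobicity(sa), sum(sa$sasa) * -0.4)

  empty <- sasa_shrake_rupley(gly$atoms[0, ])
  expect_equal(surface_hydrophobicity(empty), 0)

  # equal composition, buried vs exposed hydrophobic core
  mk <- function(core_xyz) {
    at <- dplyr::bind_rows(
      atom_row("A", 1, "", "I", core_xyz[1], core_xyz[2], core_xyz[3]),
      atom_row("A", 2, "", "G", 0, 0, 0),
      atom_row("A", 3, "", "G", 2.5, 0, 0),
      atom_row("A", 4, "", "G", 0, 2.5, 0),
      atom_row("A", 5, "", "G", 0, 0, 2.5),
      atom_row("A", 6, "", "G", 2.5, 2.5, 0),
      atom_row("A", 7, "", "G", 2.5, 0, 2.5),
      atom_row("A", 8, "", "G", 0, 2.5, 2.5),
      atom_row("A", 9, "", "G", 2.5, 2.5, 2.5))
    vhh_complex(at, "A")
  }
  buried <- mk(c(1.25, 1.25, 1.25))
  exposed <- mk(c(8, 8, 8))
  expect_lt(surface_hydrophobicity(buried), surface_hydrophobicity(exposed))
})

test_that("interface summaries apply the epitope-size filter", {
  # 5 contacting antigen residues: rejected
  small <- simple_model(cbind(c(6, 8, 10, 12, 14), 0, 0),
                        antigen_xyz = cbind(c(6, 8, 10, 12, 14), 3, 0))
  is_small <- interface_summary(small)
  expect_equal(is_small$n_epitope, 5L)
  expect_false(is_small$accepted)

  # paratope spanning CDR3 only: FR2 not involved; segment counts add up
  big <- simple_model(cbind(c(6, 8, 10, 12, 14, 16), 0, 0),
                      antigen_xyz = cbind(c(6, 8, 10, 12, 14, 16), 3, 0))
  is_big <- interface_summary(big)
  expect_true(is_big$accepted)
  expect_false(is_big$fr2_involved)
  seg_cols <- paste0("paratope_", c("FR1", "CDR1", "FR2", "CDR2",
                                    "FR3", "CDR3", "FR4"))
  expect_equal(sum(as.integer(is_big[1, seg_cols])), is_big$n_paratope)
})

test_that("secondary-structure usage counts DSSP codes", {
  m <- simple_model(cbind(c(6, 7, 8, 9, 10, 11, 12, 13, 14), 0, 0))
  cp <- imgt_cdr3_positions(9)
  m$ss <- tibble::tibble(chain = "A", position = cp$position,
                         insertion = cp$insertion,
                         ss = strsplit("CCEEETTCC", "")[[1]])
  u <- ss_usage(m, "CDR3")
  expect_equal(u$ss_E, 3 / 9)
  expect_equal(u$ss_T, 2 / 9)
  expect_equal(u$ss_C, 4 / 9)
  expect_equal(sum(as.numeric(u)), 1)

  m$ss$ss <- rep("C", 9)
  expect_equal(ss_usage(m, "CDR3")$ss_C, 1)

  m$ss <- NULL
  expect_warning(u0 <- ss_usage(m, "CDR3"), "no secondary-structure")
  expect_true(all(is.na(u0)))
})

test_that("conformation classification finds the trough of a bimodal mix", {
  set.seed(20)
  vals <- c(rnorm(250, 7, 1), rnorm(250, 15, 1))
  cls <- classify_conformation(vals)
  expect_false(cls$unimodal)
  expect_gt(cls$threshold, 9)
  expect_lt(cls$threshold, 13)
  truth <- rep(c("bent", "extended"), each = 250)
  expect_gte(mean(as.character(cls$labels) == truth), 0.99)

  expect_warning(uni <- classify_conformation(rnorm(500, 10, 1)),
                 "unimodal")
  expect_true(is.na(uni$threshold))
  expect_equal(length(unique(uni$labels)), 1L)

  expect_error(classify_conformation(c(7, 15)), ">= 20")
})
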