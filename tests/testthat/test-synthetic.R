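test_that("repertoire generation is deterministic in the seed", {
  a <- simulate_repertoire(repertoire_recipe(n = 60, seed = 4))
  b <- simulate_repertoire(repertoire_recipe(n = 60, seed = 4))
  c <- simulate_repertoire(repertoire_recipe(n = 60, seed = 5))
  expect_identical(a$sequence, b$sequence)
  expect_identical(a$count, b$count)
  expect_false(identical(a$sequence, c$sequence))
})

test_that("emitted lengths hit the recipe's nominal moments", {
  rep <- simulate_repertoire(repertoire_recipe(
    n = 10000, seed = 1, duplicate_rate = 0, outlier_rate = 0))
  len <- rep$cdr3_length
  se_mean <- 4.61 / sqrt(10000)
  se_sd <- 4.61 / sqrt(2 * 10000)
  expect_lt(abs(mean(len) - 15.73), 3 * se_mean)
  expect_lt(abs(sd(len) - 4.61), 3 * se_sd)
  expect_gte(min(len), 5L)
})

test_that("duplicate injection matches its nominal rate", {
  rep <- simulate_repertoire(repertoire_recipe(n = 4000, seed = 8,
                                               duplicate_rate = 0.1))
  n_extra <- nrow(rep) - 4000
  # binomial tolerance around 10%
  expect_lt(abs(n_extra / 4000 - 0.1), 3 * sqrt(0.1 * 0.9 / 4000))
  expect_gt(sum(duplicated(rep$sequence)), 0)
})

test_that("a zeroed charge slope leaves CDR3 charge uncorrelated", {
  rep <- simulate_repertoire(repertoire_recipe(
    n = 2500, seed = 12, germlines = default_germline_neutral(),
    charge_slope = 0, c_enrich_slope = 0, n105_decay = 0))
  rep <- filter_repertoire(rep)
  ct <- pearson_with_test(net_charge(region_slice(rep, "CDR3")),
                          rep$cdr3_length)
  expect_gt(ct$p, 0.05)
})

test_that("infeasible recipes are rejected", {
  expect_error(repertoire_recipe(length_mean = 3), ">= 5")
  expect_error(repertoire_recipe(length_std = 0), "> 0")
  bad_g <- default_germline_neutral()
  bad_g$weight <- 0.5
  expect_error(repertoire_recipe(germlines = bad_g), "sum to 1")
})

test_that("structure generation is deterministic and length-linked", {
  a <- simulate_structures(structure_recipe(n = 5, seed = 3))
  b <- simulate_structures(structure_recipe(n = 5, seed = 3))
  expect_identical(a$models[[2]]$atoms, b$models[[2]]$atoms)
  expect_identical(a$truth, b$truth)

  ss <- simulate_structures(structure_recipe(n = 80, seed = 7))
  # bent structures carry longer CDR3s on average
  expect_gt(mean(ss$truth$cdr3_length[ss$truth$conformation == "bent"]),
            mean(ss$truth$cdr3_length[ss$truth$conformation == "extended"]))
  # realized FR2-CDR3 distances track the drawn targets
  dis <- vapply(ss$models, fr2_cdr3_dis, numeric(1))
  expect_lt(max(abs(dis - ss$truth$target_dis)), 1.5)
})

test_that("generated geometry plants the intended contact patterns", {
  ss <- simulate_structures(structure_recipe(n = 30, seed = 11))
  profs <- lapply(ss$models, segment_interaction_profile)
  fr2 <- vapply(profs, function(p) p$n_pairs[p$segment == "FR2"], integer(1))
  cdr2 <- vapply(profs, function(p) p$n_pairs[p$segment == "CDR2"],
                 integer(1))
  bent <- ss$truth$conformation == "bent"
  expect_true(all(fr2[bent] > 0))
  expect_true(all(cdr2[bent] > 0))
  expect_true(all(cdr2[!bent] == 0))

  # every complex passes the minimum-epitope filter
  eps <- vapply(ss$models, function(m) interface_summary(m)$n_epitope,
                integer(1))
  expect_true(all(eps >= 6))

  # FR2 paratope involvement matches the planted flags
  fr2_inv <- vapply(ss$models,
                    function(m) interface_summary(m)$fr2_involved,
                    logical(1))
  expect_equal(fr2_inv, ss$truth$fr2_involved)
})

test_that("a bent-only recipe takes the unimodal classifier path", {
  ss <- simulate_structures(structure_recipe(n = 40, bent_fraction = 1,
                                             seed = 9))
  dis <- vapply(ss$models, fr2_cdr3_dis, numeric(1))
  expect_warning(cls <- classify_conformation(dis), "unimodal")
  expect_true(cls$unimodal)
  expect_true(all(cls$labels == "bent"))
})

test_that("conformation-specific secondary structure is emitted", {
  ss <- simulate_structures(structure_recipe(n = 40, seed = 13))
  sc <- vapply(seq_along(ss$models), function(i) {
    u <- ss_usage(ss$models[[i]], "CDR3")
    u$ss_S + u$ss_C
  }, numeric(1))
  bent <- ss$truth$conformation == "bent"
  expect_gt(mean(sc[bent]), mean(sc[!bent]))
})
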