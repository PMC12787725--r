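test_that("concentration ratios follow the BF/TF definition", {
  # root Cd over soil Cd at maturity, oracle = direct division
  expect_equal(compute_ratio(3.9195, 2.01), 1.95)
  expect_equal(compute_ratio(5, 5), 1)
  expect_equal(compute_ratio(0, 2), 0)
  expect_error(compute_ratio(1, 0), "> 0")
  expect_error(compute_ratio(-1, 2), ">= 0")
})

test_that("noise-free synthetic data inverts to the generating factors", {
  cfg <- generator_config(soil_cv = 0, tissue_noise_sd = 0, seed = 3)
  d <- generate_dataset(cfg)
  tf <- transfer_factors(d$tissue, d$soil)
  est <- dplyr::inner_join(tf[!tf$absent, ],
                           cfg$true_factors,
                           by = c("metal", "stage", "kind"))
  expect_gt(nrow(est), 60)
  expect_equal(est$mean, est$value, tolerance = 1e-12)
  # grain-based factors absent at tillering, flagged with a reason
  till_grain <- tf[tf$stage == "tillering" & tf$kind == "TF_grain_stem", ]
  expect_true(all(till_grain$absent))
  expect_match(till_grain$reason, "grain")
})

test_that("replicate noise leaves factor estimates within sampling error", {
  d <- generate_dataset(generator_config(tissue_noise_sd = 0.1, soil_cv = 0.05,
                                         n_replicates = 4, seed = 17))
  tf <- transfer_factors(d$tissue, d$soil)
  bf_cd <- tf[tf$metal == "Cd" & tf$stage == "maturity" &
                tf$kind == "BF_root_soil", ]
  # ratio = BF x lognormal noise, so SD ~ BF*sqrt(exp(sd^2)-1); 3 SE bound
  se <- 1.95 * sqrt(exp(0.1^2) - 1) / sqrt(4)
  expect_lt(abs(bf_cd$mean - 1.95), 3 * se)
  expect_equal(bf_cd$n, 4L)
  expect_false(is.na(bf_cd$sd))
})

test_that("metal rankings reproduce the reported stage orderings", {
  d <- generate_dataset(generator_config(soil_cv = 0, tissue_noise_sd = 0,
                                         seed = 1))
  tf <- transfer_factors(d$tissue, d$soil)
  # maturity root enrichment dominated by Cd, then Pb
  r <- rank_metals(tf, "BF_root_soil", "maturity")
  expect_equal(r$order, c("Cd", "Pb", "Cu", "Zn", "Cr", "As"))
  expect_false(r$ties)
  # heading stem/root transfer led by Cr, Pb weakest
  r2 <- rank_metals(tf, "TF_stem_root", "heading")
  expect_equal(r2$order, c("Cr", "Zn", "As", "Cd", "Cu", "Pb"))

  # all-equal values fall back to the fixed registry order with a tie flag
  flat <- tidyr::expand_grid(metal = hm_metals(), stage = "maturity",
                             kind = "BF_root_soil")
  flat$mean <- 1; flat$sd <- 0; flat$n <- 4L; flat$absent <- FALSE
  flat$reason <- NA_character_
  rt <- rank_metals(flat, "BF_root_soil", "maturity")
  expect_equal(rt$order, hm_metals())
  expect_true(rt$ties)

  # a missing metal is named
  expect_error(rank_metals(flat[flat$metal != "Cd", ], "BF_root_soil",
                           "maturity"), "Cd")
})

test_that("factors are scale invariant and chain to leaf/soil", {
  cfg <- generator_config(soil_cv = 0, tissue_noise_sd = 0, seed = 5)
  d <- generate_dataset(cfg)
  tf <- transfer_factors(d$tissue, d$soil)

  k <- 3.7
  d2 <- d
  d2$soil$concentration <- d2$soil$concentration * k
  d2$tissue$concentration <- d2$tissue$concentration * k
  tf2 <- transfer_factors(d2$tissue, d2$soil)
  expect_equal(tf2$mean, tf$mean, tolerance = 1e-12)

  # BF x TF_stem/root x TF_leaf/stem == C_leaf / C_soil for noise-free data
  for (m in hm_metals()) {
    chain <- prod(tf$mean[tf$metal == m & tf$stage == "heading" &
                            tf$kind %in% c("BF_root_soil", "TF_stem_root",
                                           "TF_leaf_stem")])
    leaf <- d$tissue$concentration[d$tissue$metal == m &
                                     d$tissue$stage == "heading" &
                                     d$tissue$tissue == "leaf" &
                                     d$tissue$group == "contaminated" &
                                     d$tissue$sample_id == "S01"]
    soil <- d$soil$concentration[d$soil$metal == m &
                                   d$soil$group == "contaminated" &
                                   d$soil$sample_id == "S01"]
    expect_equal(chain, leaf / soil, tolerance = 1e-12)
  }
})
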