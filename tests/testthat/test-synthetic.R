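test_that("Balding-Nichols draws have the stated mean and variance", {
  expect_equal(draw_subpop_freqs(0.3, 0, 4), rep(0.3, 4))
  set.seed(101)
  draws <- replicate(2500, draw_subpop_freqs(0.3, 0.1, 4))
  expect_equal(mean(draws), 0.3, tolerance = 0.01)
  expect_lt(abs(var(as.vector(draws)) - 0.1 * 0.3 * 0.7), 0.002)
  expect_error(draw_subpop_freqs(0, 0.1, 4), "p0")
  expect_error(draw_subpop_freqs(0.3, 1, 4), "fst")
})

test_that("cohort simulation is deterministic in the seed", {
  cfg <- scenario_config("D", n = 200)
  a <- simulate_cohort(cfg, seed = 11)
  b <- simulate_cohort(cfg, seed = 11)
  expect_identical(a$genotypes$dosages, b$genotypes$dosages)
  expect_identical(a$raw_A$values, b$raw_A$values)
  expect_identical(a$samples$bmi, b$samples$bmi)
  c_ <- simulate_cohort(cfg, seed = 12)
  expect_false(identical(a$raw_A$values, c_$raw_A$values))
})

test_that("written cohorts reload to the same data", {
  co <- simulate_cohort(sim_config(groups = c(G1 = 25, G2 = 25),
                                   n_null_variants = 3,
                                   proteins = list(protein_block(
                                     pav = TRUE, delta_A = -1,
                                     pav_freqs = c(0.4, 0.1)))), seed = 102)
  dir <- tempfile()
  write_cohort(co, dir)
  back <- load_cohort(dir)
  expect_equal(back$genotypes$dosages, co$genotypes$dosages)
  expect_equal(back$raw_A$values, co$raw_A$values, tolerance = 1e-8)
  expect_equal(back$samples$sample_id, co$samples$sample_id)
  expect_equal(back$probes$uniprot_id, co$probes$uniprot_id)
  expect_equal(sort(names(back$controls$controls)),
               sort(names(co$controls$controls)))
})

test_that("simulated genotypes follow HWE with the planted frequencies", {
  cfg <- sim_config(groups = c(G1 = 2000, G2 = 2000), n_null_variants = 0,
                    proteins = list(protein_block(cis_freq = 0.3,
                                                  n_cis_neutral = 0)))
  co <- simulate_cohort(cfg, seed = 103)
  g1 <- co$genotypes$dosages[co$samples$ancestry == "G1", "cis1"]
  expect_lt(abs(mean(g1) / 2 - 0.3), 3 * sqrt(0.3 * 0.7 / (2 * 2000)))
  expect_lt(abs(var(g1) - 2 * 0.3 * 0.7), 0.05)
})

test_that("the closed-form correlation oracle matches its frozen example", {
  # sigma_U^2 = 1, delta_A = -1, delta_B = 0.5, v_G = 0.5, noise 1 and 1
  cfg <- sim_config(groups = c(G1 = 500, G2 = 500), age_beta = 0, sex_beta = 0,
                    proteins = list(protein_block(
                      beta_cis = 0, pav = TRUE, delta_A = -1, delta_B = 0.5,
                      pav_freqs = c(0.5, 0.5), sigma_shared2 = 1)))
  un <- expected_cross_platform_r(cfg)
  ad <- expected_cross_platform_r(cfg, adjusted = TRUE)
  expect_equal(un, (1 - 0.25) / sqrt((1 + 0.5 + 1) * (1 + 0.125 + 1)),
               tolerance = 1e-12)
  expect_equal(round(un, 4), 0.3254)
  expect_equal(ad, 0.5, tolerance = 1e-12)

  # no epitope effect: adjusted equals unadjusted
  cfg0 <- sim_config(proteins = list(protein_block(pav = FALSE)))
  expect_equal(expected_cross_platform_r(cfg0),
               expected_cross_platform_r(cfg0, adjusted = TRUE))
})

test_that("empirical correlations at large n match the oracle", {
  cfg <- scenario_config("D", n = 20000)
  co <- simulate_cohort(cfg, seed = 104)
  xa <- co$raw_A$values[, 1]
  xb <- co$raw_B$values[, 1]
  expect_equal(pairwise_correlation(xa, xb)$r,
               expected_cross_platform_r(cfg), tolerance = 0.02)
  pav <- co$genotypes$dosages[, "pav1"]
  expect_equal(pairwise_correlation(pav_adjust(xa, pav),
                                    pav_adjust(xb, pav))$r,
               expected_cross_platform_r(cfg, adjusted = TRUE),
               tolerance = 0.02)
})

test_that("scenario configurations encode their qualitative regimes", {
  a <- scenario_config("A")
  expect_false(a$proteins[[1]]$pav)
  b <- scenario_config("B")
  expect_equal(b$proteins[[1]]$delta_B, 0)
  c_ <- scenario_config("C")
  expect_length(c_$proteins, 6)
  expect_length(c_$trans_hub$targets, 6)
  d <- scenario_config("D")
  expect_lt(d$proteins[[1]]$delta_A * d$proteins[[1]]$delta_B, 0)
  expect_gt(max(d$proteins[[1]]$pav_freqs) /
              (min(d$proteins[[1]]$pav_freqs) + 0.01), 5)
  e <- scenario_config("E")
  expect_equal(e$proteins[[1]]$beta_cis, 0)
  expect_equal(sum(scenario_config("A", n = 1999)$groups), 1999)
})
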