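test_that("pairwise correlation uses complete pairs and reports n", {
  x <- c(1, 2, 3, 4, NA)
  y <- c(2, 4, 6, NA, 10)
  out <- pairwise_correlation(x, y)
  expect_equal(out$r, 1)
  expect_equal(out$n, 3)
  expect_equal(pairwise_correlation(1:5, -(1:5))$r, -1)
  expect_equal(round(pairwise_correlation(c(1, 2, 3), c(1, 2, 4))$r, 4),
               0.9820)
  expect_error(pairwise_correlation(c(1, 2, NA), c(1, NA, 2)), "3 complete")
  expect_error(pairwise_correlation(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("best probe pair maximizes r with lexicographic tie-break", {
  pairs <- data.frame(probe_A = c("a2", "a1"), probe_B = c("b1", "b1"),
                      r = c(0.2, 0.8))
  expect_equal(best_probe_pair(pairs)$probe_A, "a1")
  one <- data.frame(probe_A = "a1", probe_B = "b1", r = 0.5)
  expect_equal(best_probe_pair(one)$r, 0.5)
  tie <- data.frame(probe_A = c("a2", "a1"), probe_B = c("b1", "b2"),
                    r = c(0.5, 0.5))
  expect_equal(best_probe_pair(tie)$probe_A, "a1")
  expect_error(best_probe_pair(tie[0, ]), "no candidate")
})

test_that("Cochran's Q on Fisher-z scores matches the closed form", {
  eq <- correlation_heterogeneity(rep(0.4, 4), rep(50, 4))
  expect_equal(eq$Q, 0)
  expect_equal(eq$p, 1)
  expect_equal(eq$df, 3L)

  out <- correlation_heterogeneity(c(0.5, 0), c(103, 103))
  expect_equal(out$Q, 100 * sum((atanh(c(0.5, 0)) - atanh(0.5) / 2)^2),
               tolerance = 1e-12)
  expect_equal(round(out$Q, 3), 15.087)
  expect_equal(out$p, 1.03e-4, tolerance = 0.01)
  expect_equal(out$df, 1L)
})

test_that("Q is order-invariant, non-negative, and excludes tiny groups", {
  set.seed(41)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    r <- runif(k, -0.8, 0.8)
    n <- sample(5:200, k, replace = TRUE)
    a <- correlation_heterogeneity(r, n)
    perm <- sample(k)
    b <- correlation_heterogeneity(r[perm], n[perm])
    expect_equal(a$Q, b$Q, tolerance = 1e-12)
    expect_gte(a$Q, 0)
  }
  expect_warning(out <- correlation_heterogeneity(c(0.1, 0.2, 0.3),
                                                  c(50, 3, 60)),
                 "excluded")
  expect_equal(out$df, 1L)
  expect_error(correlation_heterogeneity(c(1, 0.2), c(10, 10)), "infinite")
  expect_error(suppressWarnings(
    correlation_heterogeneity(c(0.1, 0.2), c(50, 3))), ">= 2 groups")
})

test_that("null rejection rate of the heterogeneity test is calibrated", {
  set.seed(42)
  reps <- 400
  rej <- 0
  for (i in seq_len(reps)) {
    r <- n <- numeric(4)
    for (gidx in 1:4) {
      z <- matrix(rnorm(2 * 103), ncol = 2)
      z[, 2] <- 0.3 * z[, 1] + sqrt(1 - 0.09) * z[, 2]  # common true r = 0.3
      r[gidx] <- cor(z[, 1], z[, 2]); n[gidx] <- 103
    }
    if (correlation_heterogeneity(r, n)$p < 0.05) rej <- rej + 1
  }
  expect_gt(rej / reps, 0.025)
  expect_lt(rej / reps, 0.075)
})

test_that("Bonferroni thresholds divide alpha by the test count", {
  expect_equal(signif(bonferroni_threshold(0.05, 2708), 3), 1.85e-5)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(signif(bonferroni_threshold(0.05, 2157), 3), 2.32e-5)
  expect_error(bonferroni_threshold(0.05, 0), "m")
  expect_error(bonferroni_threshold(1.5, 10), "alpha")
})

test_that("concordance table stratifies by ancestry and excludes unassigned", {
  cfg <- sim_config(groups = c(G1 = 60, G2 = 60), n_unassigned = 10,
                    n_null_variants = 2)
  co <- simulate_cohort(cfg, seed = 9)
  pa <- prepare_protein_matrix(co$raw_A, co$samples, n_protein_pcs = 0)
  pb <- prepare_protein_matrix(co$raw_B, co$samples, n_protein_pcs = 0)
  tab <- concordance_table(pa$transformed, pb$transformed, co$probes,
                           co$samples)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$n_overall, 130)           # unassigned stay in overall
  expect_equal(tab$n_G1 + tab$n_G2, 120)     # but not in the strata
  expect_equal(tab$df, 1L)
  expect_true(abs(tab$r_overall) <= 1)
})

test_that("concordance picks the strongest probe pair per target", {
  set.seed(43)
  n <- 80
  st <- make_samples(n)
  u <- rnorm(n)
  a <- cbind(good = u + rnorm(n, 0, 0.2), bad = rnorm(n))
  b <- cbind(bp = u + rnorm(n, 0, 0.2))
  rownames(a) <- rownames(b) <- st$sample_id
  pm <- probe_map(c("good", "bad", "bp"), c("A", "A", "B"),
                  rep("U1", 3), rep("G1", 3), "1", 1000)
  tab <- concordance_table(protein_matrix(a, "A", "transformed"),
                           protein_matrix(b, "B", "transformed"), pm, st)
  expect_equal(tab$probe_id_A, "good")
})
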