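test_that("PAV adjustment removes the dosage component exactly", {
  set.seed(81)
  dosage <- rbinom(200, 2, 0.4)
  m <- 0.7 * dosage
  r <- pav_adjust(m, dosage)
  expect_equal(mean(r), 0, tolerance = 1e-12)
  expect_equal(max(abs(r)), 0, tolerance = 1e-10)

  m2 <- rnorm(200)
  r2 <- pav_adjust(m2, dosage)
  expect_lt(abs(cor(r2, dosage)), 1e-8)
  expect_warning(out <- pav_adjust(m2, rep(1, 200)), "monomorphic")
  expect_equal(out, m2)
})

test_that("adjusting for an unrelated variant is a no-op", {
  set.seed(82)
  n <- 5000
  u <- rnorm(n)
  xa <- u + rnorm(n)
  xb <- u + rnorm(n)
  dosage <- rbinom(n, 2, 0.3)   # independent of both measures
  a2 <- pav_adjust(xa, dosage)
  b2 <- pav_adjust(xb, dosage)
  expect_gt(cor(xa, a2), 0.999)
  expect_lt(abs(cor(a2, b2) - cor(xa, xb)), 0.01)
})

test_that("adjusted correlation equals the partial-correlation oracle", {
  set.seed(83)
  for (i in 1:10) {
    n <- 300
    z <- rbinom(n, 2, runif(1, 0.2, 0.5))
    x <- 0.5 * z + rnorm(n)
    y <- -0.4 * z + 0.3 * x + rnorm(n)
    got <- pairwise_correlation(pav_adjust(x, z), pav_adjust(y, z))$r
    rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
    oracle <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
    expect_equal(got, oracle, tolerance = 1e-10)
  }
})

test_that("effect heterogeneity matches the closed form and calibrates", {
  eq <- effect_heterogeneity(0.4, 0.1, 0.4, 0.2)
  expect_equal(eq$Q, 0)
  expect_equal(eq$p, 1)
  out <- effect_heterogeneity(1.0, 0.1, 0.5, 0.1)
  expect_equal(out$Q, 12.5, tolerance = 1e-12)
  expect_equal(out$p, 4.07e-4, tolerance = 0.01)
  expect_error(effect_heterogeneity(1, 0, 1, 0.1), "> 0")

  set.seed(84)
  rej <- 0
  reps <- 400
  for (i in seq_len(reps)) {
    x1 <- rbinom(150, 2, 0.3); y1 <- 0.4 * x1 + rnorm(150)
    x2 <- rbinom(150, 2, 0.3); y2 <- 0.4 * x2 + rnorm(150)
    f1 <- summary(lm(y1 ~ x1))$coefficients[2, 1:2]
    f2 <- summary(lm(y2 ~ x2))$coefficients[2, 1:2]
    if (effect_heterogeneity(f1[1], f1[2], f2[1], f2[2])$p < 0.05)
      rej <- rej + 1
  }
  expect_gt(rej / reps, 0.025)
  expect_lt(rej / reps, 0.075)
})

test_that("post-adjustment signal comparison applies the LD matching rules", {
  set.seed(85)
  base <- rbinom(400, 2, 0.4)
  flip <- function(x, k) { i <- sample(400, k); x[i] <- 2 - x[i]; x }
  d <- cbind(v1 = base, v2 = flip(base, 40), v3 = rbinom(400, 2, 0.4))
  g <- make_genotypes(d)

  pre <- list(make_set("v1", "v1", 0.5, 1e-10))
  # identical set, smaller p -> strengthened
  post1 <- list(make_set("v1", "v1", 0.6, 1e-15))
  out1 <- compare_signals_post_adjustment(pre, post1, g)
  expect_equal(out1$label, "strengthened")

  # no shared member, no LD -> newly associated
  post2 <- list(make_set("v3", "v3", 0.4, 1e-9, signal = 2L))
  out2 <- compare_signals_post_adjustment(pre, post2, g)
  expect_setequal(out2$label, c("newly_associated", "lost"))

  # no shared member but leads in LD -> matched, not new
  post3 <- list(make_set("v2", "v2", 0.4, 1e-8, signal = 2L))
  out3 <- compare_signals_post_adjustment(pre, post3, g)
  expect_equal(out3$label, "attenuated")
})

test_that("adjustment report quantifies the concordance gain in scenario D", {
  cfg <- scenario_config("D", n = 2000)
  co <- simulate_cohort(cfg, seed = 86)
  xa <- rank_int(co$raw_A$values[, 1])
  xb <- rank_int(co$raw_B$values[, 1])
  rep_ <- adjustment_report(xa, xb, co$genotypes$dosages[, "pav1"],
                            co$samples)
  expect_gt(rep_$r_post, rep_$r_pre)
  expect_equal(rep_$delta, rep_$r_post - rep_$r_pre)
  expect_equal(nrow(rep_$by_group), 4)
  expect_lt(abs(cor(rep_$adjusted_A, co$genotypes$dosages[, "pav1"])), 1e-8)
})

test_that("scenario D improves concordance and reduces heterogeneity consistently", {
  cfg <- scenario_config("D", n = 2000)
  gain <- qdrop <- 0
  reps <- 30
  for (i in seq_len(reps)) {
    co <- simulate_cohort(cfg, seed = 300 + i)
    xa <- rank_int(co$raw_A$values[, 1])
    xb <- rank_int(co$raw_B$values[, 1])
    rep_ <- adjustment_report(xa, xb, co$genotypes$dosages[, "pav1"],
                              co$samples)
    if (rep_$r_post > rep_$r_pre) gain <- gain + 1
    if (rep_$Q_post < rep_$Q_pre) qdrop <- qdrop + 1
  }
  expect_gte(gain / reps, 0.95)
  expect_gte(qdrop / reps, 0.9)
})
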