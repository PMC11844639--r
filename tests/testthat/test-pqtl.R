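test_that("association scan reproduces hand-computed OLS", {
  g <- make_genotypes(matrix(c(0, 1, 2, 0, 1, 2), ncol = 1))
  y <- c(0.1, 1.2, 1.9, -0.1, 0.8, 2.1)
  # n = 6 < 10 is refused, so embed the same check at n >= 10
  expect_error(association_scan(y, g), "n < 10")
  g2 <- make_genotypes(matrix(rep(c(0, 1, 2), 4), ncol = 1))
  y2 <- rep(c(0.1, 1.2, 1.9, -0.1, 0.8, 2.1), 2)
  out <- association_scan(y2, g2)
  b <- cov(rep(c(0, 1, 2), 4), y2) / var(rep(c(0, 1, 2), 4))
  expect_equal(out$beta, b, tolerance = 1e-12)
  expect_equal(out$beta, 1, tolerance = 1e-12)
})

test_that("association scan equals the lm() oracle to machine precision", {
  set.seed(51)
  for (i in 1:15) {
    n <- sample(10:50, 1)
    d <- matrix(rbinom(n * 4, 2, runif(4, 0.1, 0.5)), n, 4, byrow = TRUE)
    y <- rnorm(n)
    g <- make_genotypes(d)
    out <- association_scan(y, g)
    for (j in 1:4) {
      if (out$flag[j] != "ok") next
      cf <- summary(lm(y ~ d[, j]))$coefficients
      expect_equal(out$beta[j], cf[2, 1], tolerance = 1e-12)
      expect_equal(out$se[j], cf[2, 2], tolerance = 1e-12)
      expect_equal(out$p[j], cf[2, 4], tolerance = 1e-12)
    }
  }
})

test_that("covariate-adjusted scan equals the multiple-regression oracle", {
  set.seed(52)
  n <- 80
  d <- matrix(rbinom(n * 3, 2, 0.3), n, 3)
  covar <- cbind(rbinom(n, 2, 0.4), rnorm(n))
  y <- 0.3 * d[, 1] + 0.5 * covar[, 1] + rnorm(n)
  out <- association_scan(y, make_genotypes(d), covariates = covar)
  for (j in 1:3) {
    cf <- summary(lm(y ~ d[, j] + covar))$coefficients
    expect_equal(out$beta[j], cf[2, 1], tolerance = 1e-10)
    expect_equal(out$se[j], cf[2, 2], tolerance = 1e-10)
    expect_equal(out$p[j], cf[2, 4], tolerance = 1e-10)
  }
})

test_that("null scan p-values are uniform", {
  set.seed(53)
  n <- 500
  d <- matrix(rbinom(n * 1000, 2, 0.3), n, 1000)
  y <- rnorm(n)
  out <- association_scan(y, make_genotypes(d))
  ks <- suppressWarnings(ks.test(out$p[out$flag == "ok"], "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("degenerate and monomorphic fits are flagged", {
  x <- rep(c(0, 1, 2), 5)
  g <- make_genotypes(cbind(v1 = x, v2 = rep(1, 15)))
  out <- association_scan(as.numeric(x), g)
  expect_equal(out$flag, c("degenerate", "monomorphic"))
  expect_equal(out$beta[1], 1)
  expect_true(is.na(out$p[2]))
})

test_that("cis window is a closed 1 Mb interval around the TSS", {
  v <- data.frame(variant_id = c("a", "b", "c", "d"),
                  chrom = c("1", "1", "1", "2"),
                  pos = c(9e6, 11000001, 10.5e6, 10e6))
  w <- cis_window(v, "1", 1e7)
  expect_setequal(w$cis, c("a", "c"))       # 9 Mb boundary included
  expect_setequal(w$trans, c("b", "d"))     # beyond 1 Mb, other chrom
})

test_that("LD r-squared behaves on aligned dosages", {
  set.seed(54)
  gi <- rbinom(1000, 2, 0.4)
  expect_equal(ld_r2(gi, gi), 1)
  expect_equal(ld_r2(gi, 2 - gi), 1)
  gj <- rbinom(1000, 2, 0.4)
  expect_lt(ld_r2(gi, gj), 0.05)
  expect_error(ld_r2(gi, rep(0, 1000)), "monomorphic")
})

test_that("Wakefield ABF matches the closed form and survives huge z", {
  expect_equal(wakefield_abf(0.6, 0.1, W = 0.04),
               sqrt(0.01 / 0.05) * exp(36 * 0.04 / (2 * 0.05)),
               tolerance = 1e-12)
  expect_equal(wakefield_abf(0.6, 0.1, W = 0.04), 8.0233e5,
               tolerance = 1e-4)
  expect_true(is.finite(wakefield_abf(5, 0.05, W = 0.04, log = TRUE)))
  expect_equal(wakefield_abf(5, 0.05, W = 0.04), Inf)  # why log exists
})

sim_signal <- function(n, m, beta, seed, freq = 0.3) {
  set.seed(seed)
  d <- matrix(rbinom(n * m, 2, freq), n, m)
  y <- beta * d[, 1] + rnorm(n)
  list(g = make_genotypes(d), y = y, causal = "v1")
}

test_that("finemap recovers a planted causal variant in its credible set", {
  hits <- 0
  reps <- 60
  for (i in seq_len(reps)) {
    s <- sim_signal(800, 51, 0.5, seed = 100 + i)
    sets <- finemap(s$y, s$g, colnames(s$g$dosages), kind = "cis",
                    probe_id = "p")
    expect_gte(length(sets), 1)
    if (s$causal %in% sets[[1]]$members) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.95)
})

test_that("finemap pips form a proper distribution and cover >= 95%", {
  s <- sim_signal(400, 8, 0.7, seed = 61)
  sets <- finemap(s$y, s$g, colnames(s$g$dosages), kind = "cis",
                  coverage = 1 - 1e-12)   # force all candidates into the set
  expect_equal(sum(sets[[1]]$pip), 1, tolerance = 1e-9)
  sets95 <- finemap(s$y, s$g, colnames(s$g$dosages), kind = "cis")
  expect_gte(sum(sets95[[1]]$pip), 0.95 - 1e-9)
  expect_true(sets95[[1]]$lead$variant_id %in% sets95[[1]]$members)
})

test_that("finemap returns empty when nothing passes the threshold", {
  set.seed(62)
  d <- matrix(rbinom(300 * 20, 2, 0.3), 300, 20)
  sets <- finemap(rnorm(300), make_genotypes(d), sprintf("v%d", 1:20),
                  kind = "cis")
  expect_length(sets, 0)
})

test_that("two independent causal cis variants yield two distinct signals", {
  ok <- 0
  reps <- 30
  for (i in seq_len(reps)) {
    set.seed(200 + i)
    n <- 800
    d <- matrix(rbinom(n * 30, 2, 0.3), n, 30)
    y <- 0.5 * d[, 1] + 0.5 * d[, 2] + rnorm(n)
    g <- make_genotypes(d)
    colnames(d) <- colnames(g$dosages)
    sets <- dedup_credible_sets(
      finemap(y, g, colnames(g$dosages), kind = "cis"), g)
    sig <- Filter(function(s) s$significant, sets)
    if (length(sig) >= 2) {
      leads <- vapply(sig[1:2], function(s) s$lead$variant_id, character(1))
      # each lead tags the causal variant it is in strongest LD with
      tag <- vapply(leads, function(l) {
        r2 <- c(v1 = ld_r2(g$dosages[, l], d[, 1]),
                v2 = ld_r2(g$dosages[, l], d[, 2]))
        if (max(r2) > 0.8) names(which.max(r2)) else NA_character_
      }, character(1))
      if (!anyNA(tag) && setequal(tag, c("v1", "v2"))) ok <- ok + 1
    }
  }
  expect_gte(ok / reps, 0.8)
})

test_that("LD-linked credible sets deduplicate to the best lead", {
  set.seed(63)
  base <- rbinom(500, 2, 0.4)
  flip <- function(x, k) { i <- sample(500, k); x[i] <- 2 - x[i]; x }
  d <- cbind(v1 = base, v2 = flip(base, 30), v3 = flip(base, 40),
             v4 = rbinom(500, 2, 0.4))
  g <- make_genotypes(d)
  s1 <- make_set("v1", "v1", 0.5, 1e-20)
  s2 <- make_set("v2", "v2", 0.4, 1e-10, signal = 2L)
  s3 <- make_set("v3", "v3", 0.3, 1e-8, signal = 3L)
  s4 <- make_set("v4", "v4", 0.3, 1e-9, signal = 4L)

  kept <- dedup_credible_sets(list(s2, s1), g)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$lead$variant_id, "v1")

  kept <- dedup_credible_sets(list(s1, s4), g)
  expect_length(kept, 2)

  # three pairwise-linked sets collapse to the single best lead
  kept <- dedup_credible_sets(list(s3, s1, s2), g)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$lead$variant_id, "v1")
})
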